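---
title: "Simulating tertiary ICU triage policies: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tertiary ICU triage policies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icutriage)
```

## The question and the model

Tertiary (ex post) triage reallocates ICU beds under crisis load: an
already-admitted patient may be discharged in favor of a waiting patient
with a better prognosis. `icutriage` compares ten reallocation policies by
their effect on mortality in the ICU, in a deliberately stylized but fully
reproducible Monte-Carlo setting:

* a fully occupied ICU of 60 beds (no natural discharges or deaths inside
  the simulated horizon);
* T = 3 consecutive daily triage timepoints;
* at each timepoint a fresh queue of q critical care patients, sampled
  i.i.d. with replacement from the cohort;
* at most m occupants exposed to displacement per timepoint ("triage
  cap") — reflecting the heavy logistics of a transfer-plus-readmission;
* six (q, m) scenarios: (12,6), (30,6), (30,12), (60,6), (60,12), (60,30);
* 1000 runs per scenario and policy, on common random numbers.

The outcome recorded after triage at each timepoint is the **realized ICU
mortality** — the fraction of the 60 current occupants whose in-hospital
death flag is set — and, as a secondary metric, the **SAPS II-predicted
mortality**, the mean Le Gall death probability of the occupants.

### Swap mechanics

Every criterion- or score-based policy reduces to an ordering key (lower =
better claim to a bed): age, first SAPS II, first TISS, secondary-diagnosis
count, total ICU length of stay, or an adjusted DIVI score. At a timepoint
the queue is sorted best first, the m worst occupants (by that same key)
form the eligible set, sorted worst first, and the pairs are swapped
positionally **while the incoming patient's key is strictly smaller** than
the incumbent's; the first non-improving pair stops the process. This
greedy pairing provably attains the minimum total key over all occupancies
reachable with at most m swaps of eligible occupants (the test suite
verifies it against exhaustive enumeration on small instances), so the
mechanics do not depend on arbitrary pairing choices.

Three policies have no key. Policy 0 never swaps. Policies 1 (random) and
2 (reverse FCFS: the most recently admitted occupants are displaced first,
queue admitted in arrival order) swap **unconditionally**, exactly
min(q, m) patients: a prognosis-blind rule has no notion of improvement,
and its role in the study is precisely to show what blind reallocation
does. Ties on a key keep the incumbent (minimal intervention); ties in
eligibility are broken by shorter elapsed ICU time, then stable order —
every tie-break is deterministic and documented.

The eligible set is defined as the m *worst* occupants under the policy's
own key. Exposure of the whole ICU with a global re-sort would make the
cap meaningless; exposing the worst incumbents is the only reading under
which an age-based example — the oldest occupants leave, the youngest
queue members enter, the rest of the queue is rejected — comes out as
illustrated in practice.

### Severity scores

The SAPS II-to-mortality conversion is the Le Gall logistic model,
`logit(p) = -7.7631 + 0.0737 S + 0.9971 ln(S + 1)`, S in [0, 163]. The
adjusted DIVI score works on a SOFA-equivalent scale obtained by the
linear max-to-max map S·24/163 (SOFA maximum 24, SAPS II maximum 163);
the value is *not* rounded before tier lookup, since any rounding
convention would be an extra assumption. The default point table uses the
DIVI guideline's four severity tiers on the SOFA scale (<6 → 1, 6–<9 → 2,
9–<12 → 3, ≥12 → 4), secondary-diagnosis tiers (≤6 → 0, 7–12 → 1,
13–18 → 2, >18 → 3) as the proxy for the limiting-prognosis criterion,
and age tiers (<50 → 0, 50–64 → 1, 65–79 → 2, ≥80 → 3). Locally agreed
point scales differ between hospitals, so the table is a plain
configuration object (`divi_point_table()`, YAML-serializable) rather
than a constant. Age is included **additively** in policy 9; treating age
only as a tie-breaker is a defensible alternative, but an additive tier
is what "summing the criteria points" implies and keeps policies 8 and 9
on the same scale.

## The synthetic cohort generator

Real ICU exports cannot be shared, so the study conditions are defined by
a generator (`generator_params()`, `generate_cohort()`) that emulates the
published cohort table of a German university hospital's fourth-pandemic-
wave ICU population: n = 1083 patients; age 64.6 ± 15.7 y; first SAPS II
35.0 ± 12.7; first TISS 9.4 ± 5.4; 12.2 ± 6.4 secondary diagnoses; 22.8%
SARS-CoV-2; ICU-LOS 4.0 ± 5.4 d; hospital LOS 17.8 ± 13.6 d; 23.8%
in-hospital mortality. Those values are the generator defaults and are
not tuning knobs.

**Marginals.** Each graded attribute is a truncated normal (age [18,100],
SAPS [0,163], TISS [0,78], counts and stays [0,∞)) whose *truncated-scale*
mean and SD are moment-matched to the table by solving for the parent
parameters; naive truncation of a normal with the printed parameters
would bias every mean upward (for ICU-LOS by more than two days). One
limit is structural: a normal truncated at 0 cannot exceed a coefficient
of variation of 1 (its exponential limit), while the printed ICU-LOS
implies cv = 5.4/4.0 = 1.35. The default therefore matches the ICU-LOS
*mean* exactly and concedes the SD (≈4 d instead of 5.4 d); the
`los_dist = "lognormal"` switch matches both moments and the right skew,
at the price of leaving the one-family design. Hospital LOS is generated
as ICU-LOS plus an independent nonnegative post-ICU duration whose
moments are chosen so the hospital-LOS mean and variance match the table;
this guarantees the containment hosp ≥ ICU per patient without biasing
either mean (clamping after independent draws would inflate the
hospital mean by about 1.3 d).

**Dependence.** A latent severity factor z drives the SAPS II rank
directly and is linked to age (ρ = 0.35), TISS (0.5), secondary diagnoses
(0.3) and ICU-LOS (0.3) through a Gaussian copula; marginals are
untouched. The real joint distribution is unpublished, but full
independence is not a neutral default here: it would make every
non-SAPS criterion exactly prognosis-free, so age-, comorbidity- and
LOS-based triage would collapse onto random reallocation and — worse — a
criterion policy's long-run mortality would then be set by the accidental
death-flag average of the fixed subpopulation it concentrates on, a
cohort-level noise term of several percentage points that no number of
simulation runs averages away. Moderate severity correlations are also
the clinically realistic choice: SAPS II itself awards age points, and
intervention intensity, comorbidity burden and length of stay all track
severity. Setting `severity_cor` to zeros restores full independence for
sensitivity analyses.

**Outcome model.** Death is Bernoulli with probability
`plogis(legall_logit(S) + c)`: the Le Gall curve shifted on the logit
scale. The offset c is calibrated by monotone root finding
(`calibrate_offset()`, tolerance 1e-6 on the mean, search bounded to
|c| ≤ 20) so that the cohort's mean death probability equals the target
mortality of 23.8%. Because the cohort's mean Le Gall prediction is about
0.2, the calibrated offset is positive — every patient's realized risk
sits above the formula's prediction. This reproduces, by construction,
the well-documented underestimation of contemporary ICU mortality by the
1993 calibration, and it is why the predicted-mortality metric sits
systematically below the realized one while ranking policies identically.
Death depends on the attributes only through SAPS II.

**Contamination.** `n_implausible` records (default 4) are appended that
each violate exactly one plausibility rule, cycling deterministically
through: two main diagnoses, missing SAPS II series, negative ICU length
of stay. Every filter rule is thereby exercised, and the default export
of 1087 records filters down to exactly 1083.

**What the generator does not emulate.** Admission dynamics,
inter-patient infection, time-varying severity, within-stay score
trajectories (later score-series entries are first-value plus noise,
present only to exercise first-score selection), the true LOS skewness
under the default family, and any joint structure beyond the single
severity factor. Passing tests on this cohort therefore demonstrate the
correctness and internal consistency of the pipeline and the qualitative
policy ordering under calibrated, severity-linked criteria — not a
quantitative reconstruction of any real hospital's tables.

## Data preparation conventions

The raw export dialect is a UTF-8 CSV with `date:value` score series and
`|`-separated ICD-10 diagnosis lists. Preparation selects the *first*
SAPS II and TISS values (earliest timestamp, ties by file order), detects
COVID-19 by ICD-10 U07.1/U07.2 or a case-insensitive free-text lexicon
{COVID, SARS-CoV-2, Coronavirus}, keeps the *first* ICU stay (earliest
start; equal starts: the longer stay), and computes lengths of stay as
whole calendar days with same-day = 0 — the natural convention for
date-only exports. Exclusion rules are applied in a fixed order (main-
diagnosis count, then missing mandatory values, then negative ICU or
hospital LOS — both stays are checked, since the source convention is
ambiguous) and a record failing several rules is reported once, under the
first. Filtering is conservative (kept + excluded = input) and idempotent.

## Simulation and evaluation choices

* Initial elapsed ICU time is discrete-uniform on {1, …, 7} days:
  `elapsed_max = 7` makes the mean initial elapsed time 4 days, the
  cohort's mean ICU-LOS; the support is configurable.
* Elapsed time advances one day per timepoint; admitted patients enter at
  0 days. Unadmitted queue patients do not carry over — queues at
  successive timepoints are independent draws.
* Each run uses substreams derived from (seed, scenario, run) for
  sampling and (seed, scenario, run, policy) for policy-internal
  randomness, so all policies see identical occupancies and queues
  (common random numbers) and every result is bit-reproducible.
* Policy 7 ranks by the *recorded* ICU-LOS attribute of a patient, not by
  elapsed simulated time: the retrospective stay length stands in for an
  LOS prediction available at decision time.
* Mortalities are recorded after triage at each timepoint; outcomes of
  discharged patients are outside the metric, which is mortality *in the
  ICU*.
* Evaluation: per (scenario, timepoint), one-way fixed-effects ANOVA over
  the 10 policies' per-run mortalities, Tukey HSD on all 45 pairs at
  α = 0.05, runs treated as independent replicates. An all-identical cell
  is reported as an exact tie (F = 0) and zero within-group variance with
  separated means as a degenerate separation (F = ∞) rather than
  failing. p-values are kept at machine precision and displayed with a
  "<1e-16" floor. Boxplot exports use the 1.5×IQR whisker convention.

## Statistical design of the test suite

The packaged checks run the full 6 × 10 × 3 design at 500 runs per cell
(the headline design uses 1000; the reduced size keeps the suite fast at
Monte-Carlo standard errors of ~0.25 percentage points per cell mean) on
the default cohort, and assert the qualitative structure: SAPS II-based
triage attains the minimum mean mortality in every cell; score-based ≤
criterion-based ≤ non-criterion class means within one Monte-Carlo
standard error; policy-4 mortality non-increasing over timepoints and
along the nested scenarios (12,6) → (30,12) → (60,30); ANOVA separating
policy 4 from policy 0 but not policy 1 from policy 0.

Two statistical subtleties are handled explicitly rather than wished
away. First, policies 0/1/2 are *exactly* equal in expectation, so any
fixed per-cell tolerance is violated somewhere among 54 pair×cell
comparisons with appreciable probability; equality is therefore tested
with paired per-run differences at a Bonferroni-adjusted per-cell
threshold plus a study-aggregate two-standard-error check. Second, with
one finite cohort the death flags are fixed realizations: in extreme
score-triaged cells (realized mortality near 3%) the sign of the
predicted-vs-realized gap rests on a handful of flags, so the systematic
underestimation is asserted globally and on the unbiased (prognosis-
blind) cells, and the argmin-preservation claim per cell.

## Known limitations

* No discharge, death or arrival process inside the 3-day horizon; the
  design isolates the reallocation effect and is not a patient-flow model.
* One cohort realization per seed: cohort-conditional values (e.g. the
  baseline mortality) fluctuate around their targets with binomial noise
  (±1.3 percentage points SD at n = 1083).
* The adjusted DIVI point table is a configurable guideline-shaped
  default, not a hospital's negotiated scale.
* The Le Gall conversion is used as published; recalibrating it is
  explicitly out of scope — the package instead measures the consequence
  of its miscalibration.
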