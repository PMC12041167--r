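# icutriage

Monte-Carlo evaluation of **tertiary (ex post) ICU triage policies**.

When a fully occupied intensive care unit faces a queue of critical care
patients, tertiary triage permits discharging an already-admitted patient in
favor of a waiting patient with a better prognosis. Whether — and by which
rule — such reallocation should happen is contested in medicine, ethics and
law. This package provides the simulation machinery to compare ten candidate
policies on the outcome that matters for the "best for the most" argument:
the resulting mortality in the ICU. It is written for biostatisticians and
health-services researchers who want to rerun, stress or extend such policy
comparisons without access to protected hospital data.

## What it computes

A cohort of ICU patients is summarized per patient by age, first SAPS II
and first TISS scores, number of secondary diagnoses, COVID-19 status,
ICU/hospital length of stay, and the in-hospital death flag. Ten policies
are compared:

| # | policy | class |
|---|--------|-------|
| 0 | no tertiary triage | baseline |
| 1 | random | non-criterion |
| 2 | "reverse" first come, first served | non-criterion |
| 3 | age | criterion |
| 4 | first SAPS II | score |
| 5 | first TISS | score |
| 6 | number of secondary diagnoses | criterion |
| 7 | ICU length of stay | criterion |
| 8 | adjusted DIVI score without age | score |
| 9 | adjusted DIVI score with age | score |

At each of T = 3 daily timepoints a queue of q patients confronts a full
60-bed ICU; at most m occupants may be displaced per timepoint. For a
policy with ordering key k (lower = better claim to a bed), the queue is
sorted best first, the m worst occupants are exposed, pairs are swapped
while the incoming key is strictly smaller, and the realized mortality
(mean death flag over the 60 occupants) and the SAPS II-predicted
mortality are recorded. Six (q, m) scenarios × 1000 runs are simulated on
common random numbers, and policies are compared per scenario/timepoint by
one-way ANOVA with Tukey-HSD post hoc tests.

Severity scoring follows the standard conversions: the SAPS II-predicted
in-hospital mortality is the inverse logit of

```
logit(p) = -7.7631 + 0.0737 * S + 0.9971 * ln(S + 1)
```

for SAPS II score S (Le Gall's logistic calibration), and the adjusted
DIVI triage score sums guideline tier points over a SOFA-equivalent
severity value (S · 24/163), the secondary-diagnosis count, and optionally
an age tier.

Because real ICU exports cannot be shared, the package includes a
calibrated synthetic cohort generator: truncated-normal marginals
moment-matched to the published cohort table (n = 1083, age 64.6 ± 15.7,
SAPS II 35.0 ± 12.7, TISS 9.4 ± 5.4, 12.2 ± 6.4 secondary diagnoses,
ICU-LOS 4.0 ± 5.4 d, hospital LOS 17.8 ± 13.6 d, 22.8% SARS-CoV-2), a
Gaussian-copula severity factor linking the attributes, and a
SAPS-linked Bernoulli death model calibrated to the realized 23.8%
in-hospital mortality — deliberately above the Le Gall prediction, whose
systematic underestimation of contemporary mortality is part of the
evaluation. A small number of deliberately implausible records exercises
the data-preparation filter.

## Worked example

```r
library(icutriage)

raw  <- generate_cohort(generator_params(seed = 1))
prep <- filter_and_prepare(raw)
print(prep$report)
#> Exclusion report: 1087 records in, 1083 kept, 4 excluded
#> main_diagnoses  missing_value   negative_los
#>              2              1              1

cohort <- score_patients(prep$patients)
res <- run_study(cohort, sim_config(n_runs = 200, seed = 99), policies = c(0, 1, 4))
subset(summarize_results(res), scenario == 1,
       c(t, policy, mean_realized, mean_predicted))
#>  t policy mean_realized mean_predicted
#>  1      0        0.2451         0.2189
#>  1      1        0.2451         0.2178
#>  1      4        0.1916         0.1662
#>  2      4        0.1546         0.1322
#>  3      4        0.1323         0.1083      (rows for policies 0/1 omitted)

anova_tukey(res, scenario = 1, t = 3)
#> One-way ANOVA across policies (scenario 1, t = 3, realized_mortality)
#>   F = 316.82, p = <1e-16
#>   Tukey HSD: 2 of 3 policy pairs significant at alpha = 0.05
```

Reading: without triage the simulated ICU mortality stays at the cohort
level (24.5%). SAPS II-based tertiary triage lowers it to 19.2% after one
timepoint and 13.2% after three (scenario 1: queue 12, cap 6; larger
scenarios reduce it further), while random reallocation is statistically
indistinguishable from doing nothing (Tukey-adjusted p = 0.999) and the
SAPS-based policy differs from both (p < 1e-16). The predicted-mortality
column sits below the realized one throughout — the Le Gall conversion
underestimates this cohort's mortality — without changing the policy
ranking.

A command-line front end over the same functions lives in
`inst/cli/triage-sim.R`:

```sh
Rscript inst/cli/triage-sim.R all --outdir reports/ --seed 1
```

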