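#' Simulation configuration
#'
#' Study defaults: a fully occupied ICU of 60 beds, 3 consecutive triage
#' timepoints (days), 1000 Monte-Carlo runs, and initial elapsed ICU time
#' drawn discrete-uniform on `{1, ..., elapsed_max}` with
#' `elapsed_max = 7` (mean 4, the cohort's mean ICU length of stay).
#'
#' @param icu_capacity Number of ICU beds.
#' @param n_timepoints Number of consecutive triage timepoints `T`.
#' @param n_runs Number of Monte-Carlo runs per scenario and policy.
#' @param elapsed_max Upper end of the initial elapsed-time distribution
#'   (days).
#' @param seed Master seed; every run uses a substream derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(icu_capacity = 60L, n_timepoints = 3L,
                       n_runs = 1000L, elapsed_max = 7L, seed = 1L) {
  config <- list(icu_capacity = as.integer(icu_capacity),
                 n_timepoints = as.integer(n_timepoints),
                 n_runs = as.integer(n_runs),
                 elapsed_max = as.integer(elapsed_max),
                 seed = as.integer(seed))
  if (any(unlist(config[1:4]) <= 0)) {
    stop("icu_capacity, n_timepoints, n_runs, elapsed_max must be positive",
         call. = FALSE)
  }
  structure(config, class = "sim_config")
}

#' The six queue/cap scenarios of the study
#'
#' Queue lengths of 12, 30 and 60 waiting critical care patients combined
#' with triage caps of 6, 12 and 30 occupants give the six studied pairs
#' (cap at most half the queue): scenario 1 = (12, 6) up to scenario
#' 6 = (60, 30).
#'
#' @return Data frame with columns `scenario_id`, `queue_size`,
#'   `triage_cap`.
#' @export
triage_scenarios <- function() {
  data.frame(
    scenario_id = 1:6,
    queue_size = c(12L, 30L, 30L, 60L, 60L, 60L),
    triage_cap = c(6L, 6L, 12L, 6L, 12L, 30L)
  )
}

# substream seed: fold integers into [0, 2^31 - 2] with a multiplicative
# mix; keeps runs reproducible and lets policies share sampling streams
mix_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (x in c(...)) {
    h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Draw a random ICU occupancy
#'
#' Samples `icu_capacity` patients from the cohort uniformly with
#' replacement and assigns each an elapsed ICU time drawn
#' discrete-uniform on `{1, ..., elapsed_max}`. Uses the current RNG
#' state; seed beforehand for reproducibility.
#'
#' @param cohort Scored patient data frame.
#' @param config A [sim_config()].
#' @return An [icu_state()].
#' @export
sample_occupancy <- function(cohort, config = sim_config()) {
  if (nrow(cohort) == 0) stop("cohort must be nonempty", call. = FALSE)
  idx <- sample.int(nrow(cohort), config$icu_capacity, replace = TRUE)
  elapsed <- sample.int(config$elapsed_max, config$icu_capacity, replace = TRUE)
  icu_state(cohort[idx, , drop = FALSE], elapsed, config$icu_capacity)
}

#' Draw a queue of waiting critical care patients
#'
#' `q` i.i.d. draws with replacement from the cohort; the draw order is
#' the arrival order used by the FCFS policy.
#'
#' @param cohort Scored patient data frame.
#' @param q Queue length.
#' @return Data frame of `q` patients in arrival order.
#' @export
sample_queue <- function(cohort, q) {
  if (nrow(cohort) == 0) stop("cohort must be nonempty", call. = FALSE)
  cohort[sample.int(nrow(cohort), q, replace = TRUE), , drop = FALSE]
}

#' Simulate one scenario under one policy
#'
#' For each of `n_runs` runs: draw an initial occupancy and `T`
#' independent queues, then for `t = 1..T` apply tertiary triage, record
#' the realized and the SAPS II-predicted ICU mortality after triage, and
#' advance every occupant's elapsed time by one day. No patient leaves or
#' arrives other than through triage during the horizon. The occupancy
#' and queue draws of a run depend only on the master seed, the scenario
#' and the run index -- not on the policy -- so different policies are
#' compared on common random numbers.
#'
#' @param cohort Scored patient data frame (see [score_patients()]).
#' @param scenario One row of [triage_scenarios()] (or a list with
#'   `scenario_id`, `queue_size`, `triage_cap`).
#' @param policy Policy id in 0-9.
#' @param config A [sim_config()].
#' @return Long-format data frame with one row per run and timepoint:
#'   `scenario, policy, run, t, realized_mortality, predicted_mortality,
#'   n_admitted, n_discharged, n_rejected`.
#' @export
run_scenario <- function(cohort, scenario, policy, config = sim_config()) {
  check_policy(policy)
  q <- as.integer(scenario$queue_size)
  cap <- as.integer(scenario$triage_cap)
  if (cap > config$icu_capacity) {
    stop("configuration error: triage cap exceeds ICU capacity", call. = FALSE)
  }
  for (col in c("died", "saps_pred_mort")) {
    if (is.null(cohort[[col]])) {
      stop("cohort lacks column '", col, "'; run score_patients() first",
           call. = FALSE)
    }
  }
  n <- nrow(cohort)
  n_beds <- config$icu_capacity
  tt <- config$n_timepoints
  keyed <- policy %in% 3:9
  keys <- if (keyed) policy_key(cohort, policy)
  died <- as.numeric(cohort$died)
  pred <- as.numeric(cohort$saps_pred_mort)

  n_rows <- config$n_runs * tt
  realized <- numeric(n_rows)
  predicted <- numeric(n_rows)
  n_adm <- integer(n_rows)
  row <- 0L
  for (r in seq_len(config$n_runs)) {
    set.seed(mix_seed(config$seed, scenario$scenario_id, r, 0L))
    occ <- sample.int(n, n_beds, replace = TRUE)
    elapsed <- sample.int(config$elapsed_max, n_beds, replace = TRUE)
    queues <- lapply(seq_len(tt), function(t) sample.int(n, q, replace = TRUE))
    set.seed(mix_seed(config$seed, scenario$scenario_id, r, 1L, policy))
    for (t in seq_len(tt)) {
      qu <- queues[[t]]
      dec <- triage_decision(policy, cap, n_beds, q,
                             keys_occ = if (keyed) keys[occ],
                             keys_queue = if (keyed) keys[qu],
                             elapsed = elapsed)
      if (length(dec$admit) > 0) {
        occ[dec$discharge] <- qu[dec$admit]
        elapsed[dec$discharge] <- 0L
      }
      row <- row + 1L
      realized[row] <- mean(died[occ])
      predicted[row] <- mean(pred[occ])
      n_adm[row] <- length(dec$admit)
      elapsed <- elapsed + 1L
    }
  }
  data.frame(
    scenario = rep(as.integer(scenario$scenario_id), n_rows),
    policy = rep(as.integer(policy), n_rows),
    run = rep(seq_len(config$n_runs), each = tt),
    t = rep(seq_len(tt), config$n_runs),
    realized_mortality = realized,
    predicted_mortality = predicted,
    n_admitted = n_adm,
    n_discharged = n_adm,
    n_rejected = rep(q, n_rows) - n_adm
  )
}

#' Run the full simulation study
#'
#' All scenarios crossed with all requested policies, each simulated with
#' [run_scenario()] on common random numbers.
#'
#' @inheritParams run_scenario
#' @param scenarios Data frame of scenarios, default [triage_scenarios()].
#' @param policies Integer vector of policy ids, default all ten.
#' @param verbose Emit a progress message per scenario/policy block?
#' @return Long-format results table keyed by
#'   `(scenario, policy, run, t)`.
#' @export
run_study <- function(cohort, config = sim_config(),
                      scenarios = triage_scenarios(), policies = 0:9,
                      verbose = FALSE) {
  blocks <- vector("list", nrow(scenarios) * length(policies))
  b <- 0L
  for (s in seq_len(nrow(scenarios))) {
    for (p in policies) {
      b <- b + 1L
      if (verbose) {
        message("scenario ", scenarios$scenario_id[s], ", policy ", p,
                " (", config$n_runs, " runs)")
      }
      blocks[[b]] <- run_scenario(cohort, scenarios[s, ], p, config)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
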