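# Builders for small in-code fixtures and the brute-force triage oracle.

# a scored patient table with controllable attributes
make_patients <- function(n, age = 60, saps = 35, tiss = 10, n_secondary = 10,
                          covid = FALSE, icu_los = 4, hosp_los = 15,
                          died = FALSE, ids = sprintf("T%03d", seq_len(n))) {
  score_patients(data.frame(
    patient_id = ids,
    age = rep_len(age, n),
    saps = rep_len(saps, n),
    tiss = rep_len(tiss, n),
    n_secondary = rep_len(n_secondary, n),
    covid = rep_len(covid, n),
    icu_los = rep_len(icu_los, n),
    hosp_los = rep_len(hosp_los, n),
    died = rep_len(died, n),
    stringsAsFactors = FALSE
  ))
}

random_patients <- function(n, prefix = "R") {
  score_patients(data.frame(
    patient_id = sprintf("%s%03d", prefix, seq_len(n)),
    age = sample(18:95, n, replace = TRUE),
    saps = sample(0:120, n, replace = TRUE),
    tiss = sample(0:40, n, replace = TRUE),
    n_secondary = sample(0:25, n, replace = TRUE),
    covid = sample(c(TRUE, FALSE), n, replace = TRUE),
    icu_los = sample(0:20, n, replace = TRUE),
    hosp_los = sample(10:40, n, replace = TRUE),
    died = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE
  ))
}

# one raw-export record as a one-row data frame, overridable by field
make_record <- function(...) {
  rec <- data.frame(
    patient_id = "X001", age = 60,
    saps_events = "2021-09-02:35",
    tiss_events = "2021-09-02:10",
    main_diagnoses = "J18.9 Pneumonia unspecified",
    secondary_diagnoses = "I10|E11.9",
    icu_start = "2021-09-02", icu_end = "2021-09-06",
    hosp_start = "2021-09-01", hosp_end = "2021-09-15",
    died = 0L, stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# Exhaustive oracle for keyed policies: the minimum achievable total
# policy key over all occupancies reachable by swapping at most `cap`
# members of the eligible set for distinct queue patients.
brute_force_min_total_key <- function(state, queue, policy, cap) {
  keys_occ <- policy_key(state$patients, policy)
  keys_q <- policy_key(queue, policy)
  elig <- eligible_set(state, policy, cap)
  best <- sum(keys_occ)
  k_max <- min(length(elig), nrow(queue))
  for (j in seq_len(k_max)) {
    out_sets <- utils::combn(elig, j, simplify = FALSE)
    in_sets <- utils::combn(seq_len(nrow(queue)), j, simplify = FALSE)
    for (os in out_sets) {
      for (is in in_sets) {
        total <- sum(keys_occ) - sum(keys_occ[os]) + sum(keys_q[is])
        best <- min(best, total)
      }
    }
  }
  best
}

# default study cohort used by the acceptance-style tests; built once per
# test session
study_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      raw <- generate_cohort(generator_params(seed = 1L))
      cache <<- score_patients(filter_and_prepare(raw)$patients)
    }
    cache
  }
})
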