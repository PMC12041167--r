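#' The ten tertiary triage policies
#'
#' Policies are numbered 0-9: 0 no tertiary triage (baseline), 1 random,
#' 2 "reverse" first come, first served (the most recently admitted
#' occupants are displaced first), 3 age, 4 first SAPS II, 5 first TISS,
#' 6 number of secondary diagnoses, 7 ICU length of stay, 8 adjusted DIVI
#' score without age, 9 adjusted DIVI score with age. For every
#' criterion- and score-based policy a lower key means a better claim to
#' a bed.
#'
#' @return `policy_labels()`: named character vector of the ten labels,
#'   names `"0"`-`"9"`. `policy_class()`: for each policy id one of
#'   `"baseline"`, `"non-criterion"`, `"criterion"`, `"score"`.
#' @export
policy_labels <- function() {
  c(`0` = "no tertiary triage", `1` = "random", `2` = "FCFS (reverse)",
    `3` = "age", `4` = "SAPS II", `5` = "TISS",
    `6` = "secondary diagnoses", `7` = "ICU LOS",
    `8` = "DIVI without age", `9` = "DIVI with age")
}

#' @rdname policy_labels
#' @param policy Integer policy id(s) in 0-9.
#' @export
policy_class <- function(policy) {
  check_policy(policy)
  cls <- c("baseline", "non-criterion", "non-criterion", "criterion",
           "score", "score", "criterion", "criterion", "score", "score")
  cls[policy + 1L]
}

check_policy <- function(policy) {
  if (any(!policy %in% 0:9)) {
    stop("policy must be an integer in 0..9", call. = FALSE)
  }
  invisible(policy)
}

#' Triage ordering key of a policy
#'
#' Returns the attribute the policy ranks patients by; a lower key means
#' a better claim to an ICU bed. Only defined for the criterion- and
#' score-based policies (3-9); the baseline and the two non-criterion
#' policies (0-2) have no ordering key.
#'
#' @param patients Scored patient data frame, see [score_patients()].
#' @param policy Policy id in 3-9.
#' @return Numeric key vector, one value per patient.
#' @export
policy_key <- function(patients, policy) {
  check_policy(policy)
  if (policy %in% 0:2) {
    stop("policy ", policy, " has no ordering key", call. = FALSE)
  }
  col <- c(`3` = "age", `4` = "saps", `5` = "tiss", `6` = "n_secondary",
           `7` = "icu_los", `8` = "divi_noage", `9` = "divi_age")[[as.character(policy)]]
  if (is.null(patients[[col]])) {
    stop("patients lack required column '", col,
         "'; run score_patients() first", call. = FALSE)
  }
  as.numeric(patients[[col]])
}

#' Construct an ICU occupancy state
#'
#' @param patients Scored patient data frame; one row per occupant. The
#'   ICU is always fully occupied: the number of rows is the capacity.
#' @param elapsed_days Nonnegative integer vector of days each occupant
#'   has already spent in the ICU.
#' @param capacity Bed count; must equal `nrow(patients)`.
#' @return An object of class `icu_state`.
#' @export
icu_state <- function(patients, elapsed_days = integer(nrow(patients)),
                      capacity = nrow(patients)) {
  if (nrow(patients) != capacity) {
    stop("state error: ICU must be fully occupied (", capacity, " beds, ",
         nrow(patients), " occupants)", call. = FALSE)
  }
  if (length(elapsed_days) != capacity || any(elapsed_days < 0)) {
    stop("elapsed_days must be nonnegative, one per occupant", call. = FALSE)
  }
  structure(list(patients = patients,
                 elapsed_days = as.integer(elapsed_days),
                 capacity = capacity),
            class = "icu_state")
}

#' Occupants exposed to tertiary triage
#'
#' For criterion- and score-based policies these are the `cap` occupants
#' with the worst (largest) policy key, ordered worst first; ties are
#' broken by smaller elapsed time, then stable input order. Policy 1
#' exposes `cap` occupants uniformly at random (consumes the RNG stream),
#' policy 2 the `cap` most recently admitted (smallest elapsed time), and
#' policy 0 exposes nobody.
#'
#' @param state An [icu_state()].
#' @param policy Policy id in 0-9.
#' @param cap Maximum number of occupants subject to triage; at most the
#'   capacity.
#' @return Integer vector of occupant indices (possibly empty), in
#'   displacement order.
#' @export
eligible_set <- function(state, policy, cap) {
  check_policy(policy)
  if (cap < 0 || cap > state$capacity) {
    stop("configuration error: cap must be in [0, capacity]", call. = FALSE)
  }
  n <- state$capacity
  k <- min(cap, n)
  if (policy == 0L || k == 0L) return(integer())
  if (policy == 1L) return(sample.int(n, k))
  if (policy == 2L) {
    return(order(state$elapsed_days, seq_len(n))[seq_len(k)])
  }
  keys <- policy_key(state$patients, policy)
  order(-keys, state$elapsed_days, seq_len(n))[seq_len(k)]
}

# Core swap decision shared by apply_triage() and the simulation fast
# path. Works on key vectors only; returns aligned admit (queue indices)
# and discharge (occupant indices) vectors.
triage_decision <- function(policy, cap, n_occ, n_queue,
                            keys_occ = NULL, keys_queue = NULL,
                            elapsed = NULL) {
  k_max <- min(n_queue, cap)
  if (policy == 0L || k_max == 0L) {
    return(list(admit = integer(), discharge = integer()))
  }
  if (policy == 1L) {
    elig <- sample.int(n_occ, min(cap, n_occ))
    k <- min(n_queue, length(elig))
    return(list(admit = sample.int(n_queue, k), discharge = elig[seq_len(k)]))
  }
  if (policy == 2L) {
    elig <- order(elapsed, seq_len(n_occ))[seq_len(min(cap, n_occ))]
    k <- min(n_queue, length(elig))
    return(list(admit = seq_len(k), discharge = elig[seq_len(k)]))
  }
  elig <- order(-keys_occ, elapsed, seq_len(n_occ))[seq_len(min(cap, n_occ))]
  q_ord <- order(keys_queue)[seq_len(k_max)]
  improving <- keys_queue[q_ord] < keys_occ[elig[seq_len(k_max)]]
  k <- match(FALSE, improving, nomatch = k_max + 1L) - 1L
  list(admit = q_ord[seq_len(k)], discharge = elig[seq_len(k)])
}

#' Apply one tertiary triage timepoint
#'
#' Confronts a fully occupied ICU with a queue of critical care patients
#' under one policy. Criterion- and score-based policies sort the queue
#' best first and the eligible occupants worst first, pair them
#' positionally and swap each pair only while the queue patient's key is
#' strictly smaller than the incumbent's; the random and reverse-FCFS
#' policies perform exactly `min(|queue|, cap)` unconditional swaps;
#' policy 0 changes nothing. Admitted patients enter with 0 elapsed days.
#' The census never changes.
#'
#' @inheritParams eligible_set
#' @param queue Scored patient data frame in arrival order.
#' @return A list with `state` (the new [icu_state()]) and `event` (a
#'   list of `admitted`, `discharged` and `rejected` patient ids, with
#'   `|admitted| == |discharged| <= min(|queue|, cap)`).
#' @export
apply_triage <- function(state, queue, policy, cap) {
  check_policy(policy)
  if (cap < 0 || cap > state$capacity) {
    stop("configuration error: cap must be in [0, capacity]", call. = FALSE)
  }
  n_queue <- nrow(queue)
  keyed <- policy %in% 3:9
  dec <- triage_decision(
    policy, cap, state$capacity, n_queue,
    keys_occ = if (keyed) policy_key(state$patients, policy),
    keys_queue = if (keyed) policy_key(queue, policy),
    elapsed = state$elapsed_days
  )
  discharged_ids <- state$patients$patient_id[dec$discharge]
  admitted_ids <- queue$patient_id[dec$admit]
  patients <- state$patients
  elapsed <- state$elapsed_days
  if (length(dec$admit) > 0) {
    patients[dec$discharge, ] <- queue[dec$admit, ]
    elapsed[dec$discharge] <- 0L
  }
  list(
    state = icu_state(patients, elapsed, state$capacity),
    event = list(admitted = admitted_ids,
                 discharged = discharged_ids,
                 rejected = setdiff(queue$patient_id, admitted_ids))
  )
}

#' ICU mortality metrics of an occupancy state
#'
#' `realized_mortality()` is the fraction of current occupants who die in
#' hospital; `predicted_mortality()` the mean SAPS II-predicted death
#' probability of the current occupants.
#'
#' @param state An [icu_state()].
#' @return A proportion in `[0, 1]`.
#' @export
realized_mortality <- function(state) {
  mean(state$patients$died)
}

#' @rdname realized_mortality
#' @export
predicted_mortality <- function(state) {
  mean(state$patients$saps_pred_mort)
}
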