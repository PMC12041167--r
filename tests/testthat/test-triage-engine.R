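test_that("policy metadata matches the ten-policy taxonomy", {
  expect_length(policy_labels(), 10)
  expect_equal(policy_class(0), "baseline")
  expect_equal(policy_class(c(1, 2)), rep("non-criterion", 2))
  expect_equal(policy_class(c(3, 6, 7)), rep("criterion", 3))
  expect_equal(policy_class(c(4, 5, 8, 9)), rep("score", 4))
  expect_error(policy_class(10), "0..9")
})

test_that("policy keys rank lower = better claim on the right attribute", {
  pts <- make_patients(2, age = c(40, 70), saps = c(20, 50), tiss = c(5, 15),
                       n_secondary = c(3, 20), icu_los = c(2, 9))
  expect_lt(policy_key(pts, 3)[1], policy_key(pts, 3)[2])
  expect_equal(policy_key(pts, 4), c(20, 50))
  expect_equal(policy_key(pts, 5), c(5, 15))
  expect_equal(policy_key(pts, 6), c(3, 20))
  expect_equal(policy_key(pts, 7), c(2, 9))
  expect_equal(policy_key(pts, 8), as.numeric(pts$divi_noage))
  # identical patients apart from the age tier: with-age DIVI separates them
  tw <- make_patients(2, age = c(45, 82))
  expect_lt(policy_key(tw, 9)[1], policy_key(tw, 9)[2])
  expect_equal(policy_key(tw, 8)[1], policy_key(tw, 8)[2])
  expect_error(policy_key(pts, 1), "no ordering key")
})

test_that("eligible set exposes the right occupants per policy", {
  set.seed(21)
  occ <- random_patients(10)
  st <- icu_state(occ, elapsed_days = c(3, 1, 5, 2, 7, 4, 6, 2, 1, 3))
  expect_equal(eligible_set(st, 0, 6), integer())
  # age policy: the oldest occupants, worst first
  e3 <- eligible_set(st, 3, 4)
  expect_equal(occ$age[e3], sort(occ$age, decreasing = TRUE)[1:4])
  # reverse FCFS: most recently admitted (smallest elapsed) first
  e2 <- eligible_set(st, 2, 3)
  expect_equal(st$elapsed_days[e2], sort(st$elapsed_days)[1:3])
  # random policy: a subset of occupants of size cap
  e1 <- eligible_set(st, 1, 5)
  expect_length(e1, 5)
  expect_true(all(e1 %in% 1:10) && !anyDuplicated(e1))
  expect_error(eligible_set(st, 3, 11), "cap")
})

test_that("a clearly better queue fills all cap slots (worked example)", {
  # scenario-1 instance: 60-bed ICU, 12 in the queue, cap 6; every queue
  # patient younger than every incumbent under age-based triage
  set.seed(2)
  icu <- make_patients(60, age = sample(55:114, 60, replace = FALSE),
                       ids = sprintf("I%03d", 1:60))
  queue <- make_patients(12, age = sample(25:50, 12, replace = FALSE),
                         ids = sprintf("Q%03d", 1:12))
  st <- icu_state(icu, elapsed_days = sample(1:7, 60, replace = TRUE))
  out <- apply_triage(st, queue, policy = 3, cap = 6)
  expect_length(out$event$admitted, 6)
  expect_length(out$event$discharged, 6)
  expect_length(out$event$rejected, 6)
  expect_equal(out$state$capacity, 60)
  expect_equal(nrow(out$state$patients), 60)
  # the six oldest incumbents leave, the six youngest queue patients enter
  expect_setequal(out$event$discharged,
                  icu$patient_id[order(-icu$age, st$elapsed_days)][1:6])
  expect_setequal(out$event$admitted,
                  queue$patient_id[order(queue$age)][1:6])
  # admitted patients start with zero elapsed days
  expect_true(all(out$state$elapsed_days[
    out$state$patients$patient_id %in% out$event$admitted] == 0))
})

test_that("no swaps happen without improvement, cap 0, or an empty queue", {
  icu <- make_patients(6, saps = c(30, 40, 20, 50, 35, 45))
  st <- icu_state(icu, elapsed_days = 1:6)
  worse <- make_patients(3, saps = c(60, 70, 80), ids = c("W1", "W2", "W3"))
  out <- apply_triage(st, worse, policy = 4, cap = 3)
  expect_length(out$event$admitted, 0)
  expect_equal(out$state$patients$patient_id, icu$patient_id)

  # tie keeps the incumbent (strict improvement required)
  tie <- make_patients(1, saps = 50, ids = "TIE")
  out_tie <- apply_triage(st, tie, policy = 4, cap = 3)
  expect_length(out_tie$event$admitted, 0)

  out0 <- apply_triage(st, worse, policy = 4, cap = 0)
  expect_length(out0$event$admitted, 0)
  out_e <- apply_triage(st, worse[0, ], policy = 4, cap = 3)
  expect_length(out_e$event$admitted, 0)
  expect_equal(realized_mortality(out_e$state), realized_mortality(st))
})

test_that("unconditional policies swap exactly min(queue, cap) patients", {
  set.seed(33)
  icu <- random_patients(8)
  st <- icu_state(icu, elapsed_days = c(5, 2, 7, 1, 3, 6, 4, 2))
  queue <- random_patients(3, prefix = "Q")
  for (p in c(1, 2)) {
    out <- apply_triage(st, queue, policy = p, cap = 2)
    expect_length(out$event$admitted, 2)
    expect_length(out$event$discharged, 2)
    expect_equal(nrow(out$state$patients), 8)
  }
  # FCFS admits in arrival order and displaces the most recent admissions
  out2 <- apply_triage(st, queue, policy = 2, cap = 2)
  expect_equal(out2$event$admitted, queue$patient_id[1:2])
  expect_setequal(out2$event$discharged, icu$patient_id[c(4, 2)])
  # policy 0 rejects the whole queue
  out0 <- apply_triage(st, queue, policy = 0, cap = 2)
  expect_length(out0$event$admitted, 0)
  expect_setequal(out0$event$rejected, queue$patient_id)
})

test_that("mortality metrics are means over the current occupants", {
  all_d <- make_patients(4, died = TRUE)
  none <- make_patients(4, died = FALSE)
  mix <- make_patients(60, died = c(rep(TRUE, 15), rep(FALSE, 45)))
  expect_equal(realized_mortality(icu_state(all_d)), 1)
  expect_equal(realized_mortality(icu_state(none)), 0)
  expect_equal(realized_mortality(icu_state(mix)), 0.25)
  one <- make_patients(3, saps = c(20, 35, 60))
  expect_equal(predicted_mortality(icu_state(one)),
               mean(saps_predicted_mortality(c(20, 35, 60))))
})

test_that("triage equals the brute-force optimum on small instances", {
  set.seed(99)
  for (trial in 1:40) {
    n_beds <- sample(3:6, 1)
    n_queue <- sample(0:4, 1)
    policy <- sample(3:9, 1)
    cap <- sample(0:n_beds, 1)
    occ <- random_patients(n_beds)
    queue <- random_patients(n_queue, prefix = "Q")
    st <- icu_state(occ, elapsed_days = sample(0:9, n_beds, replace = TRUE))
    best <- brute_force_min_total_key(st, queue, policy, cap)
    out <- apply_triage(st, queue, policy, cap)
    achieved <- sum(policy_key(out$state$patients, policy))
    expect_equal(achieved, best, info = paste("policy", policy, "trial", trial))
    # census conservation and the swap bound
    expect_equal(nrow(out$state$patients), n_beds)
    expect_lte(length(out$event$admitted), min(n_queue, cap))
    expect_equal(length(out$event$admitted), length(out$event$discharged))
  }
})

test_that("exchange optimality: no rejected patient beats a retained incumbent", {
  set.seed(123)
  for (trial in 1:20) {
    occ <- random_patients(10)
    queue <- random_patients(6, prefix = "Q")
    policy <- sample(3:9, 1)
    cap <- sample(1:5, 1)
    st <- icu_state(occ, elapsed_days = sample(1:7, 10, replace = TRUE))
    elig <- eligible_set(st, policy, cap)
    out <- apply_triage(st, queue, policy, cap)
    if (length(out$event$admitted) < min(nrow(queue), cap)) {
      # swap bound not hit: every rejected queue patient must be at least
      # as bad (key >= ) as every retained eligible incumbent
      retained <- intersect(occ$patient_id[elig],
                            out$state$patients$patient_id)
      rej_keys <- policy_key(queue, policy)[
        queue$patient_id %in% out$event$rejected]
      ret_keys <- policy_key(occ, policy)[occ$patient_id %in% retained]
      if (length(rej_keys) && length(ret_keys)) {
        expect_gte(min(rej_keys), max(ret_keys))
      }
    }
  }
})
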