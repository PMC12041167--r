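make_results <- function(groups, n_runs) {
  # groups: named list policy -> function(run) mortality
  do.call(rbind, lapply(names(groups), function(p) {
    data.frame(scenario = 1L, policy = as.integer(p), run = seq_len(n_runs),
               t = 1L,
               realized_mortality = groups[[p]](seq_len(n_runs)),
               predicted_mortality = groups[[p]](seq_len(n_runs)) * 0.8,
               n_admitted = 0L, n_discharged = 0L, n_rejected = 0L)
  }))
}

test_that("summary statistics equal a brute-force recomputation", {
  res <- make_results(list(`0` = function(r) rep(0.25, length(r)),
                           `4` = function(r) c(0.2, 0.4)[((r - 1) %% 2) + 1]),
                      n_runs = 10)
  s <- summarize_results(res)
  expect_equal(nrow(s), 2)
  s0 <- s[s$policy == 0, ]
  expect_equal(s0$mean_realized, 0.25)
  expect_equal(s0$sd_realized, 0)
  expect_equal(s0$q1, 0.25)
  expect_equal(s0$whisker_hi, 0.25)
  s4 <- s[s$policy == 4, ]
  expect_equal(s4$mean_realized, 0.3)

  # random table: group stats equal manual recomputation from raw rows
  set.seed(8)
  res2 <- data.frame(scenario = rep(1:2, each = 40),
                     policy = rep(rep(c(0L, 4L), each = 20), 2),
                     run = rep(1:20, 4), t = 1L,
                     realized_mortality = runif(80),
                     predicted_mortality = runif(80),
                     n_admitted = 0L, n_discharged = 0L, n_rejected = 0L)
  s2 <- summarize_results(res2)
  for (i in seq_len(nrow(s2))) {
    x <- res2$realized_mortality[res2$scenario == s2$scenario[i] &
                                   res2$policy == s2$policy[i]]
    expect_equal(s2$mean_realized[i], mean(x))
    expect_equal(s2$sd_realized[i], sd(x))
    expect_equal(s2$median[i], median(x))
    expect_true(s2$q1[i] <= s2$median[i] && s2$median[i] <= s2$q3[i])
  }
})

test_that("ANOVA/Tukey reproduces a hand-computed three-group example", {
  g1 <- c(18, 20, 21, 22); g2 <- c(24, 26, 27, 25); g3 <- c(30, 31, 33, 29)
  res <- make_results(list(`0` = function(r) g1, `1` = function(r) g2,
                           `2` = function(r) g3), n_runs = 4)
  out <- anova_tukey(res, scenario = 1, t = 1)
  # frozen values from explicit sum-of-squares arithmetic:
  # SSB/2 / (SSW/9) with SSB = 312.5, SSW = wait -- recompute inline
  m <- mean(c(g1, g2, g3))
  ssb <- 4 * sum((c(mean(g1), mean(g2), mean(g3)) - m)^2)
  ssw <- sum((g1 - mean(g1))^2, (g2 - mean(g2))^2, (g3 - mean(g3))^2)
  f_manual <- (ssb / 2) / (ssw / 9)
  expect_equal(out$f_statistic, f_manual, tolerance = 1e-10)
  expect_equal(out$f_statistic, 44.1, tolerance = 1e-10)
  expect_equal(out$p_value, 2.23662461565e-05, tolerance = 1e-8)
  # studentized-range p-values computed directly from ptukey
  se <- sqrt((ssw / 9) / 4)
  p_manual <- ptukey(abs(c(mean(g2) - mean(g1), mean(g3) - mean(g1),
                           mean(g3) - mean(g2))) / se, 3, 9,
                     lower.tail = FALSE)
  expect_equal(out$pairs$p_adj, p_manual, tolerance = 1e-8)
  expect_true(all(out$pairs$significant))
  expect_equal(nrow(out$pairs), 3)
})

test_that("identical groups are reported as an exact tie, not an error", {
  res <- make_results(list(`0` = function(r) rep(0.2, length(r)),
                           `1` = function(r) rep(0.2, length(r)),
                           `4` = function(r) rep(0.2, length(r))), 5)
  out <- anova_tukey(res, 1, 1)
  expect_equal(out$f_statistic, 0)
  expect_equal(out$p_value, 1)
  expect_false(any(out$pairs$significant))

  # zero within-group variance but separated means: degenerate separation
  res2 <- make_results(list(`0` = function(r) rep(0.2, length(r)),
                           `4` = function(r) rep(0.1, length(r))), 5)
  out2 <- anova_tukey(res2, 1, 1)
  expect_true(is.infinite(out2$f_statistic))
  expect_true(all(out2$pairs$significant))

  expect_error(anova_tukey(res[res$policy == 0, ], 1, 1), "at least 2")
})

test_that("Tukey flags agree in direction with a permutation test", {
  set.seed(14)
  groups <- list(`0` = function(r) 0.24 + rnorm(length(r), 0, 0.02),
                 `1` = function(r) 0.24 + rnorm(length(r), 0, 0.02),
                 `4` = function(r) 0.10 + rnorm(length(r), 0, 0.02))
  res <- make_results(groups, n_runs = 30)
  out <- anova_tukey(res, 1, 1)
  # Bonferroni-corrected two-sample permutation test per pair
  perm_p <- function(x, y, n_perm = 400) {
    obs <- abs(mean(x) - mean(y))
    pool <- c(x, y)
    hits <- replicate(n_perm, {
      idx <- sample(length(pool), length(x))
      abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
    })
    mean(hits)
  }
  alpha_bonf <- 0.05 / nrow(out$pairs)
  for (i in seq_len(nrow(out$pairs))) {
    x <- res$realized_mortality[res$policy == out$pairs$policy_a[i]]
    y <- res$realized_mortality[res$policy == out$pairs$policy_b[i]]
    p_perm <- perm_p(x, y)
    if (out$pairs$significant[i]) {
      # every Tukey-flagged difference has the same direction and is
      # also extreme under permutation
      expect_lt(p_perm, 0.05)
      expect_equal(sign(out$pairs$diff[i]), sign(mean(y) - mean(x)))
    } else {
      expect_gt(p_perm, alpha_bonf)
    }
  }
})

test_that("report export writes stable, round-trippable tables", {
  dir <- withr::local_tempdir()
  res <- make_results(list(`0` = function(r) 0.2 + r / 100,
                           `1` = function(r) 0.21 + r / 100,
                           `4` = function(r) 0.1 + r / 100), 6)
  res$t <- rep(1:2, length.out = nrow(res))
  s <- summarize_results(res)
  st <- anova_tukey_all(res)
  paths <- export_reports(s, st, dir)
  expect_true(all(file.exists(paths)))

  wide <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(nrow(wide), 2) # one row per (scenario, t)
  expect_named(wide, c("scenario", "t", "policy_0", "policy_1", "policy_4"))
  expect_equal(wide$policy_4[1],
               s$mean_realized[s$policy == 4 & s$t == 1])

  stats_tab <- read.csv(file.path(dir, "stats.csv"))
  expect_equal(nrow(stats_tab), 2)
  expect_equal(ncol(stats_tab), 4 + 3) # id cols + F + p + 3 pair columns

  box <- read.csv(file.path(dir, "boxplot_data.csv"))
  expect_equal(box$mean_realized, s$mean_realized)

  # byte-stability
  first <- readBin(paths[1], "raw", file.size(paths[1]))
  export_reports(s, st, dir)
  expect_identical(readBin(paths[1], "raw", file.size(paths[1])), first)

  # empty results: header-only files
  dir2 <- withr::local_tempdir()
  paths2 <- export_reports(summarize_results(res[0, ]), NULL, dir2)
  expect_true(all(vapply(paths2, function(p) length(readLines(p)) == 1,
                         logical(1))))
})
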