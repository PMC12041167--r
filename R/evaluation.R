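#' Summary statistics of the simulation results
#'
#' Per (scenario, timepoint, policy) group: mean and SD of the realized
#' and the SAPS II-predicted ICU mortality over the runs, plus the
#' boxplot statistics of the realized mortality (quartiles and whiskers
#' at 1.5 IQR).
#'
#' @param results Long-format results table from [run_study()] or
#'   [run_scenario()].
#' @return Data frame with one row per group, ordered by scenario,
#'   timepoint, policy.
#' @export
summarize_results <- function(results) {
  cols <- c("scenario", "t", "policy")
  if (nrow(results) == 0) {
    return(data.frame(scenario = integer(), t = integer(), policy = integer(),
                      n_runs = integer(),
                      mean_realized = numeric(), sd_realized = numeric(),
                      mean_predicted = numeric(), sd_predicted = numeric(),
                      q1 = numeric(), median = numeric(), q3 = numeric(),
                      whisker_lo = numeric(), whisker_hi = numeric()))
  }
  keys <- unique(results[cols])
  keys <- keys[order(keys$scenario, keys$t, keys$policy), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- results$scenario == keys$scenario[i] & results$t == keys$t[i] &
      results$policy == keys$policy[i]
    x <- results$realized_mortality[sel]
    p <- results$predicted_mortality[sel]
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- qs[3] - qs[1]
    data.frame(
      scenario = keys$scenario[i], t = keys$t[i], policy = keys$policy[i],
      n_runs = length(x),
      mean_realized = mean(x), sd_realized = stats::sd(x),
      mean_predicted = mean(p), sd_predicted = stats::sd(p),
      q1 = qs[1], median = qs[2], q3 = qs[3],
      whisker_lo = min(x[x >= qs[1] - 1.5 * iqr]),
      whisker_hi = max(x[x <= qs[3] + 1.5 * iqr])
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD across policies
#'
#' For one (scenario, timepoint) cell, compares the per-run ICU
#' mortalities of the policies by a one-way fixed-effects ANOVA followed
#' by Tukey's honestly-significant-difference post hoc test on all policy
#' pairs, flagged at the `alpha` level. Runs are treated as independent
#' replicates within the cell. If every run has the identical value the
#' cell is reported as an exact tie (`F = 0`, no flagged pairs) instead
#' of failing; zero within-group variance with differing group means is
#' reported as a degenerate separation (`F = Inf`).
#'
#' @param results Long-format results table.
#' @param scenario,t The cell to analyze.
#' @param alpha Significance level, default 0.05.
#' @param metric Column to compare, default `"realized_mortality"`.
#' @return A list of class `triage_anova`: `f_statistic`, `p_value`,
#'   `pairs` (data frame with `policy_a`, `policy_b`, `diff`, `lwr`,
#'   `upr`, `p_adj`, `significant`), plus the cell identifiers.
#' @export
anova_tukey <- function(results, scenario, t, alpha = 0.05,
                        metric = "realized_mortality") {
  sel <- results$scenario == scenario & results$t == t
  sub <- results[sel, , drop = FALSE]
  policies <- sort(unique(sub$policy))
  if (length(policies) < 2 || any(table(sub$policy) < 2)) {
    stop("need at least 2 policies with at least 2 runs each", call. = FALSE)
  }
  y <- sub[[metric]]
  g <- factor(sub$policy, levels = policies)
  pair_idx <- utils::combn(as.character(policies), 2)
  within_var <- tapply(y, g, stats::var)
  out <- list(scenario = scenario, t = t, metric = metric, alpha = alpha)
  if (all(within_var == 0)) {
    means <- tapply(y, g, mean)
    tied <- length(unique(means)) == 1
    diffs <- means[pair_idx[2, ]] - means[pair_idx[1, ]]
    out$f_statistic <- if (tied) 0 else Inf
    out$p_value <- if (tied) 1 else 0
    out$note <- if (tied) "exact tie: zero variance everywhere" else
      "degenerate: zero within-group variance"
    out$pairs <- data.frame(
      policy_a = as.integer(pair_idx[1, ]), policy_b = as.integer(pair_idx[2, ]),
      diff = as.numeric(diffs), lwr = as.numeric(diffs), upr = as.numeric(diffs),
      p_adj = ifelse(diffs == 0, 1, if (tied) 1 else 0),
      significant = diffs != 0 & !tied
    )
  } else {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    # TukeyHSD labels rows "b-a" for levels a < b
    lab <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    out$f_statistic <- an[["F value"]][1]
    out$p_value <- an[["Pr(>F)"]][1]
    out$note <- NA_character_
    out$pairs <- data.frame(
      policy_a = as.integer(lab[, 2]), policy_b = as.integer(lab[, 1]),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha
    )
    rownames(out$pairs) <- NULL
  }
  structure(out, class = "triage_anova")
}

#' @export
print.triage_anova <- function(x, ...) {
  pdisp <- if (x$p_value < 1e-16) "<1e-16" else format(x$p_value, digits = 3)
  cat("One-way ANOVA across policies (scenario ", x$scenario, ", t = ", x$t,
      ", ", x$metric, ")\n", sep = "")
  cat("  F = ", format(x$f_statistic, digits = 5), ", p = ", pdisp, "\n", sep = "")
  cat("  Tukey HSD:", sum(x$pairs$significant), "of", nrow(x$pairs),
      "policy pairs significant at alpha =", x$alpha, "\n")
  invisible(x)
}

#' ANOVA + Tukey HSD for every (scenario, timepoint) cell
#'
#' @inheritParams anova_tukey
#' @return List of [anova_tukey()] results, ordered by scenario then
#'   timepoint.
#' @export
anova_tukey_all <- function(results, alpha = 0.05,
                            metric = "realized_mortality") {
  cells <- unique(results[c("scenario", "t")])
  cells <- cells[order(cells$scenario, cells$t), , drop = FALSE]
  lapply(seq_len(nrow(cells)), function(i) {
    anova_tukey(results, cells$scenario[i], cells$t[i], alpha, metric)
  })
}

#' Export plot-ready report tables
#'
#' Writes four CSV files to `outdir`: `summary.csv` (mean realized ICU
#' mortality, rows = scenario x timepoint, one column per policy),
#' `summary_predicted.csv` (same layout for the predicted-mortality
#' metric), `stats.csv` (per scenario x timepoint: ANOVA F and p plus the
#' 45 Tukey-adjusted pairwise p-values), and `boxplot_data.csv` (the
#' boxplot statistics of [summarize_results()] in long format). Output is
#' byte-stable given identical inputs.
#'
#' @param summary Output of [summarize_results()].
#' @param stats Output of [anova_tukey_all()] (may be `NULL` to skip
#'   `stats.csv` content, writing headers only).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
export_reports <- function(summary, stats, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, c("summary.csv", "summary_predicted.csv",
                               "stats.csv", "boxplot_data.csv"))
  wide <- function(value_col) {
    cells <- unique(summary[c("scenario", "t")])
    cells <- cells[order(cells$scenario, cells$t), , drop = FALSE]
    policies <- sort(unique(summary$policy))
    out <- cells
    for (p in policies) {
      out[[paste0("policy_", p)]] <- vapply(seq_len(nrow(cells)), function(i) {
        v <- summary[[value_col]][summary$scenario == cells$scenario[i] &
                                    summary$t == cells$t[i] &
                                    summary$policy == p]
        if (length(v) == 1) v else NA_real_
      }, numeric(1))
    }
    rownames(out) <- NULL
    out
  }
  if (nrow(summary) > 0) {
    utils::write.csv(wide("mean_realized"), paths[1], row.names = FALSE)
    utils::write.csv(wide("mean_predicted"), paths[2], row.names = FALSE)
  } else {
    utils::write.csv(data.frame(scenario = integer(), t = integer()),
                     paths[1], row.names = FALSE)
    utils::write.csv(data.frame(scenario = integer(), t = integer()),
                     paths[2], row.names = FALSE)
  }
  if (!is.null(stats) && length(stats) > 0) {
    stat_rows <- lapply(stats, function(s) {
      row <- data.frame(scenario = s$scenario, t = s$t,
                        f_statistic = s$f_statistic, p_value = s$p_value)
      pcols <- stats::setNames(
        as.list(s$pairs$p_adj),
        paste0("p_", s$pairs$policy_a, "_vs_", s$pairs$policy_b)
      )
      cbind(row, as.data.frame(pcols))
    })
    utils::write.csv(do.call(rbind, stat_rows), paths[3], row.names = FALSE)
  } else {
    utils::write.csv(data.frame(scenario = integer(), t = integer(),
                                f_statistic = numeric(), p_value = numeric()),
                     paths[3], row.names = FALSE)
  }
  utils::write.csv(summary, paths[4], row.names = FALSE)
  invisible(paths)
}
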