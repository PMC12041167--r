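#' SAPS II logit of in-hospital death (Le Gall logistic model)
#'
#' Computes the linear predictor of the original SAPS II-to-mortality
#' conversion, `-7.7631 + 0.0737 * S + 0.9971 * log(S + 1)` for a SAPS II
#' score `S`. The inverse logit of this value is the predicted probability
#' of dying in hospital.
#'
#' @param saps Numeric vector of SAPS II scores, each in `[0, 163]`.
#' @return Numeric vector of logits; strictly increasing in `saps`.
#' @seealso [saps_predicted_mortality()]
#' @export
#' @examples
#' legall_logit(c(0, 35, 163))
legall_logit <- function(saps) {
  check_saps_range(saps)
  -7.7631 + 0.0737 * saps + 0.9971 * log(saps + 1)
}

#' SAPS II-predicted in-hospital mortality
#'
#' Inverse-logit of [legall_logit()]; the probability of in-hospital death
#' predicted from the (first) SAPS II score alone.
#'
#' @inheritParams legall_logit
#' @return Probabilities in `(0, 1)`, strictly increasing in `saps`.
#' @export
#' @examples
#' saps_predicted_mortality(35) # about 0.17
saps_predicted_mortality <- function(saps) {
  stats::plogis(legall_logit(saps))
}

#' Map a SAPS II score onto the SOFA scale
#'
#' Linear scale adjustment based on the maxima of the two scores
#' (SOFA: 24, SAPS II: 163): `saps * 24 / 163`. The result is real-valued;
#' no rounding is applied before tier lookup in [divi_points()].
#'
#' @inheritParams legall_logit
#' @return SOFA-equivalent points in `[0, 24]`.
#' @export
saps_to_sofa_equivalent <- function(saps) {
  check_saps_range(saps)
  saps * 24 / 163
}

check_saps_range <- function(saps) {
  if (!is.numeric(saps) || anyNA(saps) || any(saps < 0) || any(saps > 163)) {
    stop("SAPS II scores must be numeric and within [0, 163]", call. = FALSE)
  }
  invisible(saps)
}

#' Point table for the adjusted DIVI triage score
#'
#' The adjusted DIVI score sums tier points over three criteria: disease
#' severity on the SOFA-equivalent scale (the SAPS II score rescaled by
#' [saps_to_sofa_equivalent()]), limiting prognosis proxied by the number
#' of secondary diagnoses, and -- optionally -- age as a secondary
#' criterion. Lower totals indicate a better prognosis.
#'
#' Each criterion is a step function: `breaks` are the strictly increasing
#' lower bounds of the upper tiers, `points` has one more element than
#' `breaks` and gives the points of each tier (half-open intervals,
#' left-closed at each break). The default table uses the four-tier
#' structure of the DIVI guideline on the SOFA scale (`< 6` -> 1,
#' `[6, 9)` -> 2, `[9, 12)` -> 3, `>= 12` -> 4), secondary-diagnosis tiers
#' `<= 6` -> 0, `7..12` -> 1, `13..18` -> 2, `> 18` -> 3, and age tiers
#' `< 50` -> 0, `50..64` -> 1, `65..79` -> 2, `>= 80` -> 3. The table is a
#' plain config object so that a locally agreed point scale can be dropped
#' in (see [read_divi_table()]).
#'
#' @param sofa,secdiag,age Lists with numeric `breaks` and integer `points`.
#' @return An object of class `divi_point_table`.
#' @export
divi_point_table <- function(sofa = list(breaks = c(6, 9, 12), points = c(1, 2, 3, 4)),
                             secdiag = list(breaks = c(7, 13, 19), points = c(0, 1, 2, 3)),
                             age = list(breaks = c(50, 65, 80), points = c(0, 1, 2, 3))) {
  table <- list(sofa = sofa, secdiag = secdiag, age = age)
  for (nm in names(table)) {
    crit <- table[[nm]]
    if (!is.list(crit) || !all(c("breaks", "points") %in% names(crit))) {
      stop("DIVI criterion '", nm, "' needs 'breaks' and 'points'", call. = FALSE)
    }
    if (length(crit$points) != length(crit$breaks) + 1L) {
      stop("DIVI criterion '", nm, "': need one more point value than breaks",
           call. = FALSE)
    }
    if (is.unsorted(crit$breaks, strictly = TRUE)) {
      stop("DIVI criterion '", nm, "': breaks must be strictly increasing",
           call. = FALSE)
    }
    if (any(crit$points < 0) || any(crit$points != round(crit$points))) {
      stop("DIVI criterion '", nm, "': points must be nonnegative integers",
           call. = FALSE)
    }
  }
  structure(table, class = "divi_point_table")
}

tier_points <- function(x, criterion) {
  criterion$points[findInterval(x, criterion$breaks) + 1L]
}

#' Adjusted DIVI triage points for prepared patients
#'
#' Sums the severity tier points (on the SOFA-equivalent scale) and the
#' secondary-diagnosis tier points, plus the age tier points when
#' `include_age = TRUE`. Lower totals = better prognosis.
#'
#' @param patients Data frame with columns `saps`, `n_secondary` and (if
#'   `include_age`) `age`; typically the output of [filter_and_prepare()].
#' @param include_age Add the age criterion points?
#' @param table A [divi_point_table()].
#' @return Integer vector of point totals, one per patient.
#' @export
divi_points <- function(patients, include_age = FALSE, table = divi_point_table()) {
  if (!inherits(table, "divi_point_table")) {
    table <- do.call(divi_point_table, table)
  }
  pts <- tier_points(saps_to_sofa_equivalent(patients$saps), table$sofa) +
    tier_points(patients$n_secondary, table$secdiag)
  if (include_age) {
    pts <- pts + tier_points(patients$age, table$age)
  }
  as.integer(pts)
}

#' Attach severity-score columns to a prepared cohort
#'
#' Adds the columns used by the score-based triage policies and the
#' evaluation metric: `saps_pred_mort` (Le Gall predicted mortality),
#' `sofa_equiv` (SOFA-equivalent scale value), `divi_noage` and `divi_age`
#' (adjusted DIVI totals without/with the age criterion).
#'
#' @param patients Prepared cohort, see [filter_and_prepare()].
#' @param table A [divi_point_table()].
#' @return `patients` with the four score columns appended.
#' @export
score_patients <- function(patients, table = divi_point_table()) {
  patients$saps_pred_mort <- saps_predicted_mortality(patients$saps)
  patients$sofa_equiv <- saps_to_sofa_equivalent(patients$saps)
  patients$divi_noage <- divi_points(patients, include_age = FALSE, table = table)
  patients$divi_age <- divi_points(patients, include_age = TRUE, table = table)
  patients
}

#' Read / write a DIVI point table as YAML
#'
#' @param path File path.
#' @param table A [divi_point_table()].
#' @return `read_divi_table()` returns a validated `divi_point_table`;
#'   `write_divi_table()` invisibly returns `path`.
#' @export
read_divi_table <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(divi_point_table, raw)
}

#' @rdname read_divi_table
#' @export
write_divi_table <- function(table, path) {
  yaml::write_yaml(lapply(unclass(table), function(x) {
    list(breaks = as.numeric(x$breaks), points = as.integer(x$points))
  }), path)
  invisible(path)
}
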