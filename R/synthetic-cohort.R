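#' Parameters for the synthetic raw-export generator
#'
#' Defaults reproduce the marginal statistics of the fourth-pandemic-wave
#' ICU cohort the simulation study is calibrated to: n = 1083 patients,
#' age 64.6 +/- 15.7 years, first SAPS II 35.0 +/- 12.7, first TISS
#' 9.4 +/- 5.4, 12.2 +/- 6.4 secondary diagnoses, 22.8% SARS-CoV-2,
#' ICU length of stay 4.0 +/- 5.4 days, hospital length of stay
#' 17.8 +/- 13.6 days, and 23.8% in-hospital mortality. In addition,
#' `n_implausible` deliberately corrupted records (default 4) are appended
#' so that the plausibility filter of [filter_and_prepare()] is exercised.
#'
#' @param n_patients Number of plausible patients.
#' @param age_mean,age_sd Age marginal (years), truncated to `[18, 100]`.
#' @param saps_mean,saps_sd First SAPS II marginal, truncated to `[0, 163]`.
#' @param tiss_mean,tiss_sd First TISS marginal, truncated to `[0, 78]`.
#' @param secdiag_mean,secdiag_sd Secondary-diagnosis count marginal,
#'   truncated to `[0, Inf)` and rounded to a nonnegative integer.
#' @param covid_fraction Probability of a SARS-CoV-2 diagnosis (ICD-10
#'   U07.1 among the secondary diagnoses).
#' @param icu_los_mean,icu_los_sd ICU length-of-stay marginal (days).
#' @param hosp_los_mean,hosp_los_sd Hospital length-of-stay marginal (days);
#'   generated as ICU LOS plus a nonnegative post-ICU duration so that the
#'   hospital stay always contains the ICU stay.
#' @param target_mortality Marginal in-hospital death fraction the
#'   SAPS-linked death model is calibrated to, see [calibrate_offset()].
#' @param n_implausible Number of corrupted records appended after the
#'   plausible ones, cycling through three defects: two main diagnoses,
#'   missing SAPS II series, negative ICU length of stay.
#' @param los_dist `"truncnorm"` (default) or `"lognormal"` for the two
#'   length-of-stay marginals. The truncated normal matches the LOS mean
#'   exactly but cannot reach a coefficient of variation above 1, so its
#'   SD undershoots strongly right-skewed targets; the log-normal switch
#'   matches both moments.
#' @param severity_cor Named vector of Gaussian-copula correlations
#'   between the latent severity factor (whose rank order is the SAPS II
#'   score) and the other graded attributes. Marginal distributions are
#'   unaffected. Defaults reflect that in real ICU cohorts severity
#'   correlates moderately with age (SAPS II itself awards age points),
#'   intervention intensity (TISS), comorbidity burden and ICU length of
#'   stay. Set all entries to 0 for fully independent attributes.
#' @param seed Integer seed; the generated export is byte-for-byte
#'   reproducible from it.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_patients = 1083L,
                             age_mean = 64.6, age_sd = 15.7,
                             saps_mean = 35.0, saps_sd = 12.7,
                             tiss_mean = 9.4, tiss_sd = 5.4,
                             secdiag_mean = 12.2, secdiag_sd = 6.4,
                             covid_fraction = 0.228,
                             icu_los_mean = 4.0, icu_los_sd = 5.4,
                             hosp_los_mean = 17.8, hosp_los_sd = 13.6,
                             target_mortality = 0.238,
                             n_implausible = 4L,
                             los_dist = c("truncnorm", "lognormal"),
                             severity_cor = c(age = 0.35, tiss = 0.5,
                                              secdiag = 0.3, icu_los = 0.3),
                             seed = 1L) {
  params <- list(
    n_patients = as.integer(n_patients),
    age_mean = age_mean, age_sd = age_sd,
    saps_mean = saps_mean, saps_sd = saps_sd,
    tiss_mean = tiss_mean, tiss_sd = tiss_sd,
    secdiag_mean = secdiag_mean, secdiag_sd = secdiag_sd,
    covid_fraction = covid_fraction,
    icu_los_mean = icu_los_mean, icu_los_sd = icu_los_sd,
    hosp_los_mean = hosp_los_mean, hosp_los_sd = hosp_los_sd,
    target_mortality = target_mortality,
    n_implausible = as.integer(n_implausible),
    los_dist = match.arg(los_dist),
    severity_cor = severity_cor,
    seed = as.integer(seed)
  )
  needed <- c("age", "tiss", "secdiag", "icu_los")
  if (!all(needed %in% names(params$severity_cor)) ||
      any(abs(params$severity_cor) > 1)) {
    stop("severity_cor needs entries age, tiss, secdiag, icu_los in [-1, 1]",
         call. = FALSE)
  }
  sds <- params[grep("_sd$", names(params))]
  if (any(unlist(sds) <= 0)) {
    stop("all *_sd parameters must be > 0", call. = FALSE)
  }
  if (params$covid_fraction < 0 || params$covid_fraction > 1 ||
      params$target_mortality <= 0 || params$target_mortality >= 1) {
    stop("covid_fraction must be in [0,1] and target_mortality in (0,1)",
         call. = FALSE)
  }
  if (params$n_patients < 0 || params$n_implausible < 0) {
    stop("n_patients and n_implausible must be nonnegative", call. = FALSE)
  }
  structure(params, class = "generator_params")
}

#' SAPS-linked death probability with a calibration offset
#'
#' Probability of in-hospital death used by the synthetic cohort's outcome
#' model: the inverse logit of `legall_logit(saps) + offset`. With
#' `offset = 0` this is exactly the Le Gall SAPS II-predicted mortality;
#' a positive offset shifts every patient's risk upward on the logit
#' scale. The construction makes realized mortality exceed the Le Gall
#' prediction by design once the offset is calibrated to a cohort death
#' fraction above the mean prediction, reproducing the systematic
#' underestimation seen when the 1993 formula is applied to contemporary
#' cohorts.
#'
#' @inheritParams legall_logit
#' @param offset Real shift on the logit scale.
#' @return Probabilities in `(0, 1)`, strictly increasing in both
#'   arguments.
#' @export
death_probability <- function(saps, offset = 0) {
  stats::plogis(legall_logit(saps) + offset)
}

#' Calibrate the death-model offset to a target mortality
#'
#' Finds the offset `c` such that the mean of
#' `death_probability(saps, c)` over the supplied SAPS II sample equals
#' `target_mortality` (to within 1e-6). The mean is strictly increasing
#' in `c`, so the root is unique; the search is restricted to
#' `c` in `[-20, 20]` on the logit scale and targets outside the
#' attainable range raise an error.
#'
#' @param saps_sample Nonempty numeric vector of SAPS II scores.
#' @param target_mortality Target death fraction in `(0, 1)`.
#' @return The calibrated offset (a single real number).
#' @export
calibrate_offset <- function(saps_sample, target_mortality) {
  if (length(saps_sample) == 0) {
    stop("saps_sample must be nonempty", call. = FALSE)
  }
  if (target_mortality <= 0 || target_mortality >= 1) {
    stop("target_mortality must be in (0, 1)", call. = FALSE)
  }
  lg <- legall_logit(saps_sample)
  f <- function(c) mean(stats::plogis(lg + c)) - target_mortality
  if (f(-20) > 0 || f(20) < 0) {
    stop("calibration error: target mortality not attainable for this sample",
         call. = FALSE)
  }
  stats::uniroot(f, c(-20, 20), tol = 1e-10)$root
}

# small fixed ICD-10 pools for synthetic diagnoses
main_dx_pool <- c(
  "J96.0 Acute respiratory failure",
  "J18.9 Pneumonia unspecified",
  "A41.9 Sepsis unspecified organism",
  "I21.4 Acute subendocardial myocardial infarction",
  "I63.9 Cerebral infarction",
  "N17.9 Acute kidney failure",
  "K72.0 Acute hepatic failure",
  "S06.5 Traumatic subdural haemorrhage"
)
secondary_dx_pool <- c(
  "I10", "E11.9", "E78.5", "N18.3", "I48.9", "J44.9", "E66.9", "F17.2",
  "I25.1", "E03.9", "D64.9", "K21.9", "M81.9", "G47.3", "Z95.1", "E87.6",
  "I50.9", "J96.1", "N39.0", "E86"
)

fmt_events <- function(dates, values) {
  paste(paste0(format(dates, "%Y-%m-%d"), ":", values), collapse = ";")
}

#' Generate a synthetic raw patient export
#'
#' Draws `n_patients + n_implausible` raw records with the marginal
#' structure described in [generator_params()]. Continuous attributes come
#' from truncated normal distributions whose truncated-scale moments are
#' matched to the target mean/SD; the in-hospital death flag is Bernoulli
#' with a SAPS-linked probability calibrated via [calibrate_offset()] so
#' the cohort death fraction matches `target_mortality` in expectation.
#' Graded attributes share a latent severity factor through a Gaussian
#' copula (see `severity_cor` in [generator_params()]); death depends on
#' the attributes only through SAPS II. The trailing
#' `n_implausible` records each violate exactly one plausibility rule,
#' cycling through: two main diagnoses, missing SAPS II series, negative
#' ICU length of stay.
#'
#' @param params A [generator_params()] object.
#' @return A data frame in the raw-export layout (one row per record):
#'   `patient_id, age, saps_events, tiss_events, main_diagnoses,
#'   secondary_diagnoses, icu_start, icu_end, hosp_start, hosp_end, died`.
#'   Event series encode `date:value` pairs separated by `;`, diagnosis
#'   lists are `|`-separated with the ICD-10 code first.
#' @seealso [write_export()], [parse_export()], [filter_and_prepare()]
#' @export
generate_cohort <- function(params = generator_params()) {
  if (!inherits(params, "generator_params")) {
    params <- do.call(generator_params, params)
  }
  n <- params$n_patients + params$n_implausible
  if (n == 0) {
    return(empty_export())
  }
  withr::with_seed(params$seed, generate_cohort_impl(params, n))
}

generate_cohort_impl <- function(params, n) {
  # latent severity factor: drives the SAPS II rank; the other graded
  # attributes are tied to it by a Gaussian copula (marginals unchanged)
  z <- stats::rnorm(n)
  r <- params$severity_cor
  cop_u <- function(rho) {
    stats::pnorm(rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
  }
  saps <- round(rtrunc_matched(n, params$saps_mean, params$saps_sd, 0, 163,
                               u = stats::pnorm(z)))
  age <- round(rtrunc_matched(n, params$age_mean, params$age_sd, 18, 100,
                              u = cop_u(r[["age"]])))
  tiss <- round(rtrunc_matched(n, params$tiss_mean, params$tiss_sd, 0, 78,
                               u = cop_u(r[["tiss"]])))
  n_sec <- round(rtrunc_matched(n, params$secdiag_mean, params$secdiag_sd,
                                0, Inf, u = cop_u(r[["secdiag"]])))
  u_los <- cop_u(r[["icu_los"]])
  extra_mean <- params$hosp_los_mean - params$icu_los_mean
  extra_sd <- sqrt(max(params$hosp_los_sd^2 - params$icu_los_sd^2, 1e-8))
  if (params$los_dist == "lognormal") {
    icu_los <- round(qlnorm_moments(u_los, params$icu_los_mean,
                                    params$icu_los_sd))
    extra <- round(rlnorm_moments(n, extra_mean, extra_sd))
  } else {
    icu_los <- round(rtrunc_matched(n, params$icu_los_mean,
                                    params$icu_los_sd, 0, Inf, u = u_los))
    extra <- round(rtrunc_matched(n, extra_mean, extra_sd, 0, Inf))
  }
  hosp_los <- icu_los + extra
  covid <- stats::runif(n) < params$covid_fraction

  hosp_start <- as.Date("2021-09-01") + sample.int(122L, n, replace = TRUE) - 1L
  hosp_end <- hosp_start + hosp_los
  gap <- floor(stats::runif(n) * (hosp_los - icu_los + 1))
  icu_start <- hosp_start + gap
  icu_end <- icu_start + icu_los

  main_dx <- sample(main_dx_pool, n, replace = TRUE)
  n_sec_eff <- ifelse(covid & n_sec == 0, 1, n_sec)
  secondary <- vapply(seq_len(n), function(i) {
    k <- n_sec_eff[i]
    if (k == 0) return("")
    codes <- sample(secondary_dx_pool, k, replace = TRUE)
    if (covid[i]) codes[1] <- "U07.1"
    paste(codes, collapse = "|")
  }, character(1))

  saps_events <- character(n)
  tiss_events <- character(n)
  n_events <- sample.int(3L, n, replace = TRUE)
  for (i in seq_len(n)) {
    k <- n_events[i]
    dts <- icu_start[i] + seq_len(k) - 1L
    sv <- c(saps[i], pmin(pmax(round(saps[i] + stats::rnorm(k - 1, 0, 6)), 0), 163))
    tv <- c(tiss[i], pmin(pmax(round(tiss[i] + stats::rnorm(k - 1, 0, 3)), 0), 78))
    saps_events[i] <- fmt_events(dts, sv[seq_len(k)])
    tiss_events[i] <- fmt_events(dts, tv[seq_len(k)])
  }

  plausible <- seq_len(n) <= params$n_patients
  offset <- if (any(plausible)) {
    calibrate_offset(saps[plausible], params$target_mortality)
  } else {
    0
  }
  died <- as.integer(stats::runif(n) < death_probability(saps, offset))

  records <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = as.numeric(age),
    saps_events = saps_events,
    tiss_events = tiss_events,
    main_diagnoses = main_dx,
    secondary_diagnoses = secondary,
    icu_start = format(icu_start, "%Y-%m-%d"),
    icu_end = format(icu_end, "%Y-%m-%d"),
    hosp_start = format(hosp_start, "%Y-%m-%d"),
    hosp_end = format(hosp_end, "%Y-%m-%d"),
    died = died,
    stringsAsFactors = FALSE
  )
  attr(records, "death_model_offset") <- offset

  if (params$n_implausible > 0) {
    rows <- which(!plausible)
    rules <- rep_len(1:3, length(rows))
    for (j in seq_along(rows)) {
      i <- rows[j]
      if (rules[j] == 1L) {
        records$main_diagnoses[i] <- paste(records$main_diagnoses[i],
                                           "B99 Other infectious disease",
                                           sep = "|")
      } else if (rules[j] == 2L) {
        records$saps_events[i] <- ""
      } else {
        records$icu_end[i] <- format(as.Date(records$icu_start[i]) - 2L,
                                     "%Y-%m-%d")
      }
    }
  }
  records
}

# log-normal parameterized by its own mean and sd
rlnorm_moments <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

qlnorm_moments <- function(u, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::qlnorm(u, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

empty_export <- function() {
  data.frame(
    patient_id = character(), age = numeric(),
    saps_events = character(), tiss_events = character(),
    main_diagnoses = character(), secondary_diagnoses = character(),
    icu_start = character(), icu_end = character(),
    hosp_start = character(), hosp_end = character(),
    died = integer(), stringsAsFactors = FALSE
  )
}

#' Write a raw export to CSV
#'
#' Serializes records in the raw-export dialect (UTF-8, header row,
#' comma-separated, ISO-8601 dates); the output round-trips losslessly
#' through [parse_export()] and is byte-for-byte reproducible.
#'
#' @param records Raw-export data frame, see [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_export <- function(records, path) {
  utils::write.csv(records[, names(empty_export())], path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
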