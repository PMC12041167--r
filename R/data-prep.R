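#' Parse a raw patient export
#'
#' Reads a CSV file in the raw-export dialect (see [generate_cohort()] for
#' the column layout) into a data frame of raw records. Values are kept in
#' their serialized form; downstream accessors such as [first_scores()]
#' parse the encoded series and diagnosis lists.
#'
#' @param path Path to the CSV file.
#' @return Raw-export data frame; zero rows for a header-only file.
#' @export
parse_export <- function(path) {
  template <- empty_export()
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character",
                             fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(template), names(records))
  if (length(missing_cols) > 0) {
    stop("export format error: missing columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- records[, names(template), drop = FALSE]
  records$age <- suppressWarnings(as.numeric(records$age))
  records$died <- suppressWarnings(as.integer(records$died))
  records
}

# "date:value;date:value" -> data.frame(timestamp, value) in timestamp
# order, ties kept in file order
parse_events <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(timestamp = as.Date(character()), value = numeric()))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  ts <- as.Date(vapply(parts, `[`, character(1), 1), format = "%Y-%m-%d")
  val <- as.numeric(vapply(parts, `[`, character(1), 2))
  if (anyNA(ts) || anyNA(val)) {
    stop("format error in event series: ", s, call. = FALSE)
  }
  ord <- order(ts) # stable: equal timestamps keep file order
  data.frame(timestamp = ts[ord], value = val[ord])
}

parse_dx <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  strsplit(s, "|", fixed = TRUE)[[1]]
}

dx_code <- function(dx) vapply(strsplit(dx, " ", fixed = TRUE), `[`,
                               character(1), 1)

#' First SAPS II and TISS scores of a record
#'
#' Selects, from each score series, the value with the earliest timestamp;
#' ties are broken by file order. An empty series yields `NA` (a missing
#' value that triggers exclusion in [filter_and_prepare()]).
#'
#' @param record A single raw record (one-row data frame or list) with
#'   `saps_events` and `tiss_events` fields.
#' @return Named numeric vector `c(saps = , tiss = )`.
#' @export
first_scores <- function(record) {
  first_of <- function(s) {
    ev <- parse_events(s)
    if (nrow(ev) == 0) NA_real_ else ev$value[1]
  }
  c(saps = first_of(record$saps_events), tiss = first_of(record$tiss_events))
}

#' Detect a COVID-19 diagnosis in a raw record
#'
#' `TRUE` iff any main or secondary diagnosis carries ICD-10 code U07.1 or
#' U07.2, or its free text matches the case-insensitive lexicon
#' \{COVID, SARS-CoV-2, Coronavirus\}.
#'
#' @inheritParams first_scores
#' @return Logical flag.
#' @export
detect_covid <- function(record) {
  dx <- c(parse_dx(record$main_diagnoses), parse_dx(record$secondary_diagnoses))
  if (length(dx) == 0) return(FALSE)
  any(dx_code(dx) %in% c("U07.1", "U07.2")) ||
    any(grepl("covid|sars-cov-2|coronavirus", dx, ignore.case = TRUE))
}

#' First ICU stay of a record
#'
#' The `icu_start`/`icu_end` fields may hold several `;`-separated stays.
#' Returns the interval with the earliest start; equal starts are resolved
#' in favour of the longer interval.
#'
#' @inheritParams first_scores
#' @return Named Date vector `c(icu_start = , icu_end = )`, or `NA`s when
#'   no interval is present.
#' @export
select_first_icu_stay <- function(record) {
  starts <- as.Date(parse_dx_dates(record$icu_start), format = "%Y-%m-%d")
  ends <- as.Date(parse_dx_dates(record$icu_end), format = "%Y-%m-%d")
  if (length(starts) == 0 || length(starts) != length(ends) ||
      anyNA(starts) || anyNA(ends)) {
    return(c(icu_start = as.Date(NA), icu_end = as.Date(NA)))
  }
  # earliest start; tie -> longer stay (larger end)
  best <- order(starts, -as.numeric(ends))[1]
  c(icu_start = starts[best], icu_end = ends[best])
}

parse_dx_dates <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Length of stay in whole calendar days
#'
#' Calendar-day difference `end - start`; a same-day stay counts as 0 days.
#' The result may be negative for implausible input, which is caught by
#' the plausibility filter rather than here.
#'
#' @param start,end Dates or ISO-8601 date strings.
#' @return Integer number of days.
#' @export
compute_los <- function(start, end) {
  to_date <- function(x) {
    if (inherits(x, "Date")) return(x)
    as.Date(as.character(x), format = "%Y-%m-%d")
  }
  s <- to_date(start)
  e <- to_date(end)
  if (anyNA(s) || anyNA(e)) stop("format error: unparseable date", call. = FALSE)
  as.integer(e - s)
}

#' Filter raw records and derive analysis-ready patients
#'
#' Applies the three plausibility rules in order -- (1) not exactly one
#' main diagnosis, (2) a missing mandatory value (age, either score
#' series, any stay date, death flag), (3) negative ICU or hospital length
#' of stay -- and, for the retained records, derives the analysis-ready
#' patient table: first SAPS II and TISS scores, secondary-diagnosis
#' count, COVID-19 flag, first-ICU-stay and hospital lengths of stay, and
#' the death flag. A record violating several rules is reported once,
#' under the first rule in that order.
#'
#' @param records Raw-export data frame, see [parse_export()].
#' @return A list with `patients` (data frame with columns `patient_id,
#'   age, saps, tiss, n_secondary, covid, icu_los, hosp_los, died`) and
#'   `report` (an `exclusion_report` with `n_input`, `n_kept` and one row
#'   per exclusion: `patient_id`, `rule`).
#' @export
filter_and_prepare <- function(records) {
  n <- nrow(records)
  keep <- logical(n)
  rule <- character(n)
  prepared <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[i, ]
    n_main <- length(parse_dx(rec$main_diagnoses))
    scores <- tryCatch(first_scores(rec), error = function(e) c(saps = NA, tiss = NA))
    stay <- select_first_icu_stay(rec)
    hosp_ok <- !is.na(rec$hosp_start) && nzchar(rec$hosp_start) &&
      !is.na(rec$hosp_end) && nzchar(rec$hosp_end)
    if (n_main != 1L) {
      rule[i] <- "main_diagnoses"
      next
    }
    if (is.na(rec$age) || anyNA(scores) || anyNA(stay) || !hosp_ok ||
        is.na(rec$died)) {
      rule[i] <- "missing_value"
      next
    }
    icu_los <- compute_los(stay[["icu_start"]], stay[["icu_end"]])
    hosp_los <- compute_los(rec$hosp_start, rec$hosp_end)
    if (icu_los < 0 || hosp_los < 0) {
      rule[i] <- "negative_los"
      next
    }
    keep[i] <- TRUE
    prepared[[i]] <- data.frame(
      patient_id = rec$patient_id,
      age = rec$age,
      saps = scores[["saps"]],
      tiss = scores[["tiss"]],
      n_secondary = length(parse_dx(rec$secondary_diagnoses)),
      covid = detect_covid(rec),
      icu_los = icu_los,
      hosp_los = hosp_los,
      died = rec$died == 1L,
      stringsAsFactors = FALSE
    )
  }
  patients <- if (any(keep)) {
    out <- do.call(rbind, prepared[keep])
    rownames(out) <- NULL
    out
  } else {
    data.frame(patient_id = character(), age = numeric(), saps = numeric(),
               tiss = numeric(), n_secondary = integer(), covid = logical(),
               icu_los = integer(), hosp_los = integer(), died = logical(),
               stringsAsFactors = FALSE)
  }
  report <- structure(
    list(n_input = n, n_kept = sum(keep),
         exclusions = data.frame(patient_id = records$patient_id[!keep],
                                 rule = rule[!keep],
                                 stringsAsFactors = FALSE)),
    class = "exclusion_report"
  )
  list(patients = patients, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report:", x$n_input, "records in,", x$n_kept, "kept,",
      nrow(x$exclusions), "excluded\n")
  if (nrow(x$exclusions) > 0) {
    print(table(x$exclusions$rule))
  }
  invisible(x)
}
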