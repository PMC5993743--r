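#' Time-slice configuration
#'
#' Slice 1 is the baseline window `[-1, 0]` months around diagnosis; slices
#' `2..m` tile `(0, horizon]` in half-open windows of `interval_months`
#' each, so every measurement time in `(0, horizon]` maps to exactly one
#' slice.  With the defaults (3-month interval, 24-month horizon) there are
#' m = 9 slices with windows `[-1,0], (0,3], (3,6], ..., (21,24]`.
#'
#' @param interval_months positive slice width in months.
#' @param horizon_months positive horizon; must be a multiple of the interval.
#' @return an object of class `slice_config` with elements `interval`,
#'   `horizon` and `m` (number of slices including baseline).
#' @export
slice_config <- function(interval_months = 3, horizon_months = 24) {
  stopifnot(interval_months > 0, horizon_months > 0)
  k <- horizon_months / interval_months
  if (abs(k - round(k)) > 1e-8)
    stop("horizon_months must be a multiple of interval_months")
  structure(list(interval = interval_months, horizon = horizon_months,
                 m = as.integer(round(k)) + 1L),
            class = "slice_config")
}

#' @export
print.slice_config <- function(x, ...) {
  cat(sprintf("slice_config: m = %d slices, interval %g mo, horizon %g mo\n",
              x$m, x$interval, x$horizon))
  invisible(x)
}

#' Slice window and slice lookup
#'
#' @param cfg a [slice_config()].
#' @param slice_idx slice index in `1..m`.
#' @return `slice_window` returns `c(lo, hi)`; the window is `[lo, hi]` for
#'   slice 1 and `(lo, hi]` otherwise.
#' @export
slice_window <- function(cfg, slice_idx) {
  stopifnot(slice_idx >= 1L, slice_idx <= cfg$m)
  if (slice_idx == 1L) return(c(-1, 0))
  c((slice_idx - 2) * cfg$interval, (slice_idx - 1) * cfg$interval)
}

#' @rdname slice_window
#' @param time_months vector of measurement times (months from diagnosis).
#' @return `slice_of_time` returns the slice index for each time, or `NA`
#'   for times outside `[-1, horizon]`.
#' @export
slice_of_time <- function(cfg, time_months) {
  idx <- ifelse(time_months <= 0, 1L,
                as.integer(ceiling(time_months / cfg$interval)) + 1L)
  idx[time_months < -1 | time_months > cfg$horizon] <- NA_integer_
  idx
}

#' Assemble a cohort from long-format tables
#'
#' @param measurements data frame `patient_id, time_months, variable, value`.
#' @param outcomes data frame `patient_id, os_months, event` (event 1 =
#'   death, 0 = censored).
#' @param treatments optional data frame `patient_id, time_months, kind`
#'   with kind in surgery/ablation/tace/other.
#' @return an object of class `sp_cohort`.
#' @export
cohort <- function(measurements, outcomes, treatments = NULL) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stop(what, " table missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  need(measurements, c("patient_id", "time_months", "variable", "value"),
       "measurements")
  need(outcomes, c("patient_id", "os_months", "event"), "outcomes")
  if (is.null(treatments))
    treatments <- data.frame(patient_id = character(), time_months = numeric(),
                             kind = character(), stringsAsFactors = FALSE)
  need(treatments, c("patient_id", "time_months", "kind"), "treatments")
  outcomes$patient_id <- as.character(outcomes$patient_id)
  measurements$patient_id <- as.character(measurements$patient_id)
  treatments$patient_id <- as.character(treatments$patient_id)
  if (nrow(outcomes) == 0L) stop("empty cohort: outcomes table has no rows")
  if (anyDuplicated(outcomes$patient_id))
    stop("patient_id must be unique in the outcomes table")
  if (any(outcomes$os_months < 0)) stop("os_months must be >= 0")
  if (!all(outcomes$event %in% c(0, 1))) stop("event must be 0/1")
  # no measurements after death / loss to follow-up
  mx <- tapply(measurements$time_months, measurements$patient_id, max)
  os <- stats::setNames(outcomes$os_months, outcomes$patient_id)
  bad <- names(mx)[!is.na(os[names(mx)]) & mx > os[names(mx)] + 1e-9]
  if (length(bad))
    stop("measurements recorded after os_months for patient(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  orphan <- setdiff(measurements$patient_id, outcomes$patient_id)
  if (length(orphan))
    stop("measurements for patient(s) absent from outcomes: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  structure(list(measurements = measurements, outcomes = outcomes,
                 treatments = treatments), class = "sp_cohort")
}

#' @export
print.sp_cohort <- function(x, ...) {
  cat(sprintf("sp_cohort: %d patients, %d measurements, %d treatment events, %d deaths\n",
              nrow(x$outcomes), nrow(x$measurements), nrow(x$treatments),
              sum(x$outcomes$event)))
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' @param measurements_csv,outcomes_csv,treatments_csv file paths; the
#'   treatments file is optional.
#' @return an `sp_cohort`.
#' @export
read_cohort <- function(measurements_csv, outcomes_csv, treatments_csv = NULL) {
  rd <- function(p) utils::read.csv(p, stringsAsFactors = FALSE,
                                    fileEncoding = "UTF-8")
  tr <- if (!is.null(treatments_csv)) rd(treatments_csv) else NULL
  cohort(rd(measurements_csv), rd(outcomes_csv), tr)
}

#' Write a cohort to CSV files
#'
#' @param x an `sp_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "sp_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("measurements.csv", "outcomes.csv", "treatments.csv"))
  utils::write.csv(x$measurements, paths[1], row.names = FALSE)
  utils::write.csv(x$outcomes, paths[2], row.names = FALSE)
  utils::write.csv(x$treatments, paths[3], row.names = FALSE)
  invisible(paths)
}
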