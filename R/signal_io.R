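#' Construct an ECG record
#'
#' An `ecg_record` holds a single-lead ECG waveform together with its
#' sampling rate. Amplitudes are in arbitrary units (nominally mV); the
#' recommended acquisition setting for the normative protocol is Lead II at
#' 2048 Hz during five minutes of seated rest.
#'
#' @param samples numeric vector of amplitudes, length >= 2.
#' @param sampling_rate_hz sampling rate in Hz, > 0.
#' @param lead_label lead description, e.g. `"II"`.
#' @param subject_id subject identifier.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, sampling_rate_hz, lead_label = "II",
                       subject_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("ecg_record: need at least 2 samples", call. = FALSE)
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("ecg_record: sampling_rate_hz must be positive", call. = FALSE)
  if (anyNA(samples))
    stop("ecg_record: samples contain NA", call. = FALSE)
  structure(
    list(samples = samples,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         lead_label = as.character(lead_label),
         subject_id = as.character(subject_id)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record: %d samples at %g Hz (%.1f s), lead %s\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz, x$lead_label))
  invisible(x)
}

#' Construct an interbeat-interval series
#'
#' An `ibi_series` is the substrate of every HRV index: an ordered sequence
#' of normal-to-normal intervals in milliseconds, with the cumulative beat
#' onset times kept alongside (beat_times_ms has one more element than
#' intervals_ms and starts at the series origin).
#'
#' @param intervals_ms numeric vector of positive intervals (ms).
#' @param beat_times_ms optional cumulative beat times (ms); reconstructed
#'   by cumulative sum from 0 when absent. Successive differences must
#'   equal `intervals_ms` to within 1e-9 ms.
#' @param subject_id subject identifier.
#' @return an object of class `ibi_series`.
#' @export
ibi_series <- function(intervals_ms, beat_times_ms = NULL,
                       subject_id = NA_character_) {
  intervals_ms <- as.numeric(intervals_ms)
  if (length(intervals_ms) == 0L)
    stop("ibi_series: no intervals", call. = FALSE)
  if (anyNA(intervals_ms) || any(intervals_ms <= 0))
    stop("ibi_series: intervals must be positive and non-missing",
         call. = FALSE)
  if (is.null(beat_times_ms)) {
    beat_times_ms <- c(0, cumsum(intervals_ms))
  } else {
    beat_times_ms <- as.numeric(beat_times_ms)
    if (length(beat_times_ms) != length(intervals_ms) + 1L)
      stop("ibi_series: beat_times_ms must have length(intervals) + 1",
           call. = FALSE)
    if (max(abs(diff(beat_times_ms) - intervals_ms)) > 1e-9)
      stop("ibi_series: beat time differences disagree with intervals",
           call. = FALSE)
  }
  structure(
    list(intervals_ms = intervals_ms,
         beat_times_ms = beat_times_ms,
         subject_id = as.character(subject_id)),
    class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("IBI series: %d intervals, span %.1f s, mean RR %.1f ms\n",
              length(x$intervals_ms), diff(range(x$beat_times_ms)) / 1000,
              mean(x$intervals_ms)))
  invisible(x)
}

#' Read a single-lead ECG from CSV
#'
#' Expects a two-column numeric CSV with header (`time_s`, `amplitude`);
#' the sampling rate is inferred as the reciprocal of the median time step.
#' The time column must be strictly increasing.
#'
#' @param path path to the CSV file.
#' @param subject_id optional subject identifier attached to the record.
#' @return an [ecg_record()].
#' @export
read_ecg <- function(path, subject_id = NA_character_) {
  if (!file.exists(path)) stop("read_ecg: file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, header = TRUE)
  if (ncol(d) < 2L)
    stop("read_ecg: expected columns time_s, amplitude", call. = FALSE)
  t <- as.numeric(d[[1L]]); a <- as.numeric(d[[2L]])
  if (anyNA(t) || anyNA(a))
    stop("read_ecg: non-numeric values in time or amplitude column",
         call. = FALSE)
  if (length(t) < 2L) stop("read_ecg: fewer than 2 samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("read_ecg: time column not strictly increasing", call. = FALSE)
  rate <- 1 / stats::median(dt)
  ecg_record(a, rate, subject_id = subject_id)
}

#' Write an ECG record to CSV
#'
#' Inverse of [read_ecg()]: writes `time_s, amplitude` with time built from
#' the sampling rate.
#'
#' @param ecg an [ecg_record()].
#' @param path output path.
#' @export
write_ecg <- function(ecg, path) {
  stopifnot(inherits(ecg, "ecg_record"))
  n <- length(ecg$samples)
  d <- data.frame(time_s = (seq_len(n) - 1L) / ecg$sampling_rate_hz,
                  amplitude = ecg$samples)
  utils::write.csv(format(d, digits = 15, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an interbeat-interval file
#'
#' Plain-text RR export convention: one interval per line, milliseconds,
#' blank lines ignored. `units = "s"` rescales second-valued files.
#'
#' @param path path to the text file.
#' @param units `"ms"` (default) or `"s"`.
#' @param subject_id optional subject identifier.
#' @return an [ibi_series()] with beat times reconstructed from 0 by
#'   cumulative sum.
#' @export
read_ibi <- function(path, units = c("ms", "s"),
                     subject_id = NA_character_) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("read_ibi: file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("read_ibi: no intervals", call. = FALSE)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad) > 0L)
    stop(sprintf("read_ibi: invalid interval %s at line %d",
                 trimws(lines[keep[bad[1L]]]), keep[bad[1L]]),
         call. = FALSE)
  if (units == "s") vals <- vals * 1000
  ibi_series(vals, subject_id = subject_id)
}

#' Write an interbeat-interval file
#'
#' @param ibi an [ibi_series()].
#' @param path output path.
#' @export
write_ibi <- function(ibi, path) {
  stopifnot(inherits(ibi, "ibi_series"))
  writeLines(format(ibi$intervals_ms, digits = 15, scientific = FALSE,
                    trim = TRUE), path)
  invisible(path)
}

norm_table_cols <- c("stratum_age_lo", "stratum_age_hi", "sex",
                     "index_name", "mean", "sd", "n")

#' Construct a normative table
#'
#' A `norm_table` is a data frame of per-stratum reference cells: one row
#' per (age bin x sex x index) with the stratum mean, standard deviation
#' and sample size. `sex` is `"male"`, `"female"` or `"pooled"` (a pooled
#' row matches subjects of either sex).
#'
#' @param entries data frame with columns `stratum_age_lo`,
#'   `stratum_age_hi`, `sex`, `index_name`, `mean`, `sd`, `n`.
#' @param provenance free-text provenance string.
#' @return an object of classes `norm_table`, `data.frame`.
#' @export
norm_table <- function(entries, provenance = "") {
  entries <- as.data.frame(entries)
  missing_cols <- setdiff(norm_table_cols, names(entries))
  if (length(missing_cols) > 0L)
    stop("norm_table: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  entries <- entries[norm_table_cols]
  if (any(!entries$sex %in% c("male", "female", "pooled")))
    stop("norm_table: sex must be male, female or pooled", call. = FALSE)
  if (any(entries$sd <= 0))
    stop("norm_table: sd must be > 0", call. = FALSE)
  if (any(entries$n < 1))
    stop("norm_table: n must be >= 1", call. = FALSE)
  if (any(entries$stratum_age_hi <= entries$stratum_age_lo))
    stop("norm_table: age_hi must exceed age_lo", call. = FALSE)
  key <- paste(entries$stratum_age_lo, entries$stratum_age_hi,
               entries$sex, entries$index_name)
  if (anyDuplicated(key))
    stop("norm_table: duplicate (stratum, index) entries", call. = FALSE)
  attr(entries, "provenance") <- provenance
  class(entries) <- c("norm_table", "data.frame")
  entries
}

#' Read / write a normative table
#'
#' CSV columns are exactly `stratum_age_lo, stratum_age_hi, sex,
#' index_name, mean, sd, n`. Values are written as fixed-precision decimal
#' text so that a write/read round trip is lossless.
#'
#' @param path path to the CSV file.
#' @return [read_norm_table()] returns a [norm_table()].
#' @export
read_norm_table <- function(path) {
  if (!file.exists(path)) stop("read_norm_table: file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  prov <- attr(d, "provenance")
  norm_table(d, provenance = if (is.null(prov)) "" else prov)
}

#' @rdname read_norm_table
#' @param table a [norm_table()].
#' @export
write_norm_table <- function(table, path) {
  stopifnot(inherits(table, "norm_table"))
  d <- as.data.frame(table)
  for (col in c("mean", "sd"))
    d[[col]] <- format(d[[col]], digits = 15, scientific = FALSE,
                       trim = TRUE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

cohort_required_cols <- c("subject_id", "age", "sex", "group")
cohort_score_cols <- c("bdi_total", "bdi_cognitive", "bdi_somatic",
                       "bai_total", "bai_cognitive", "bai_somatic")

#' Validate a cohort table
#'
#' A cohort table is an ordinary data frame with one row per participant:
#' `subject_id`, `age` (years, in \[20, 70)), `sex` (`male`/`female`),
#' `group` (`HC`/`MDD`), the six questionnaire columns (BDI-II and BAI
#' totals and cognitive/somatic subscales, each total in \[0, 63\]) and,
#' optionally, HRV index columns named as in [hrv_index_names].
#'
#' @param d data frame to validate.
#' @param require_indices if TRUE, the six reported index columns must be
#'   present.
#' @return the validated data frame (invisibly classed `cohort_table`).
#' @export
as_cohort_table <- function(d, require_indices = FALSE) {
  d <- as.data.frame(d)
  missing_cols <- setdiff(cohort_required_cols, names(d))
  if (length(missing_cols) > 0L)
    stop("cohort table: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (any(!d$sex %in% c("male", "female")))
    stop("cohort table: sex must be male or female", call. = FALSE)
  if (any(!d$group %in% c("HC", "MDD")))
    stop("cohort table: group must be HC or MDD", call. = FALSE)
  if (any(d$age < 20 | d$age >= 70))
    stop("cohort table: ages must lie in [20, 70)", call. = FALSE)
  for (col in intersect(c("bdi_total", "bai_total"), names(d)))
    if (any(d[[col]] < 0 | d[[col]] > 63, na.rm = TRUE))
      stop("cohort table: ", col, " outside [0, 63]", call. = FALSE)
  if (require_indices) {
    missing_idx <- setdiff(reported_index_names(), names(d))
    if (length(missing_idx) > 0L)
      stop("cohort table: missing HRV index column(s): ",
           paste(missing_idx, collapse = ", "), call. = FALSE)
  }
  if (!inherits(d, "cohort_table")) class(d) <- c("cohort_table",
                                                  "data.frame")
  d
}

#' Read / write a cohort table
#'
#' @param path CSV path.
#' @param require_indices passed to [as_cohort_table()].
#' @return [read_cohort()] returns a validated cohort data frame.
#' @export
read_cohort <- function(path, require_indices = FALSE) {
  if (!file.exists(path)) stop("read_cohort: file not found: ", path,
                               call. = FALSE)
  as_cohort_table(utils::read.csv(path, stringsAsFactors = FALSE),
                  require_indices = require_indices)
}

#' @rdname read_cohort
#' @param cohort a cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Names of the HRV index fields
#'
#' `hrv_index_names()` lists all ten fields computed per recording;
#' `reported_index_names()` lists the six indices that enter norms and
#' Z-scores (SDNN, RMSSD and the four log-transformed spectral indices).
#'
#' @return character vector of field names.
#' @export
hrv_index_names <- function() {
  c("sdnn_ms", "rmssd_ms", "lf_ms2", "hf_ms2", "tp_ms2", "lf_hf",
    "ln_lf", "ln_hf", "ln_lf_hf", "ln_tp")
}

#' @rdname hrv_index_names
#' @export
reported_index_names <- function() {
  c("sdnn_ms", "rmssd_ms", "ln_lf", "ln_hf", "ln_lf_hf", "ln_tp")
}
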