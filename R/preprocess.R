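#' Cleaning policy for interbeat-interval artifact removal
#'
#' Artifact beats are removed (never interpolated) by two gates: an
#' absolute physiological range and a relative deviation from the running
#' median of the five most recent accepted intervals. Deletion rather than
#' interpolation avoids injecting spectral power that was never measured.
#'
#' @param min_ms lower absolute bound (ms), default 300.
#' @param max_ms upper absolute bound (ms), default 2000.
#' @param max_rel_dev maximum fractional deviation from the running
#'   median, default 0.20.
#' @param warn_fraction removed fraction above which the series is flagged
#'   low quality, default 0.20.
#' @param max_fraction removed fraction above which the recording is
#'   rejected as unusable, default 0.50.
#' @return a list of class `cleaning_policy`.
#' @export
cleaning_policy <- function(min_ms = 300, max_ms = 2000,
                            max_rel_dev = 0.20, warn_fraction = 0.20,
                            max_fraction = 0.50) {
  stopifnot(min_ms > 0, max_ms > min_ms,
            max_rel_dev > 0, warn_fraction > 0,
            max_fraction > warn_fraction)
  structure(list(min_ms = min_ms, max_ms = max_ms,
                 max_rel_dev = max_rel_dev,
                 warn_fraction = warn_fraction,
                 max_fraction = max_fraction),
            class = "cleaning_policy")
}

#' Detect R-peaks in a single-lead ECG
#'
#' A deterministic Pan-Tompkins-style detector: band-pass 5-30 Hz
#' (zero-phase Butterworth), differentiate, square, moving-window
#' integration over 150 ms, adaptive amplitude threshold, 250 ms
#' refractory period, and final refinement of each fiducial point to the
#' local maximum of the band-passed signal within +/- 50 ms.
#'
#' @param ecg an [ecg_record()]; sampling rate must be >= 100 Hz and the
#'   record at least 10 s long.
#' @return integer vector of strictly increasing sample indices (1-based);
#'   empty, with a warning, when no QRS-like activity is found.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- ecg$sampling_rate_hz
  if (fs < 100)
    stop("detect_r_peaks: sampling rate must be >= 100 Hz", call. = FALSE)
  x <- ecg$samples
  if (length(x) / fs < 10)
    stop("detect_r_peaks: recording shorter than 10 s", call. = FALSE)

  if (max(abs(x - x[1L])) < .Machine$double.eps * 100) {
    warning("detect_r_peaks: flat signal, no peaks found")
    return(integer(0))
  }

  bp <- signal::butter(2, c(5, 30) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  d <- c(0, diff(xf)) * fs
  sq <- d^2
  win <- max(1L, round(0.150 * fs))
  integ <- stats::filter(sq, rep(1 / win, win), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  thr <- 0.20 * stats::quantile(integ, 0.99, names = FALSE)
  if (thr <= 0) {
    warning("detect_r_peaks: no peaks found")
    return(integer(0))
  }

  above <- integ > thr
  refractory <- round(0.250 * fs)
  half_win <- round(0.050 * fs)
  n <- length(x)

  # candidate regions = runs of supra-threshold integrated energy
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- cbind(starts[r$values], ends[r$values])
  if (nrow(regions) == 0L) {
    warning("detect_r_peaks: no peaks found")
    return(integer(0))
  }

  peaks <- integer(0)
  for (k in seq_len(nrow(regions))) {
    i0 <- regions[k, 1L]; i1 <- regions[k, 2L]
    cand <- i0 - 1L + which.max(integ[i0:i1])
    # refine to local max of the band-passed signal within +/- 50 ms
    lo <- max(1L, cand - half_win); hi <- min(n, cand + half_win)
    apex <- lo - 1L + which.max(xf[lo:hi])
    if (length(peaks) > 0L && apex - peaks[length(peaks)] < refractory) {
      # keep the larger of the two competing candidates
      if (xf[apex] > xf[peaks[length(peaks)]])
        peaks[length(peaks)] <- apex
    } else {
      peaks <- c(peaks, apex)
    }
  }
  if (length(peaks) == 0L) warning("detect_r_peaks: no peaks found")
  peaks
}

#' Convert R-peak sample indices to an interbeat-interval series
#'
#' @param peaks strictly increasing sample indices.
#' @param rate sampling rate in Hz.
#' @param subject_id optional subject identifier.
#' @return an [ibi_series()] with intervals `diff(peaks) / rate * 1000` ms.
#' @export
peaks_to_ibi <- function(peaks, rate, subject_id = NA_character_) {
  if (length(peaks) < 2L)
    stop("peaks_to_ibi: need at least 2 peaks", call. = FALSE)
  if (any(diff(peaks) <= 0))
    stop("peaks_to_ibi: peaks must be strictly increasing", call. = FALSE)
  stopifnot(rate > 0)
  intervals <- diff(peaks) / rate * 1000
  times <- (peaks - peaks[1L]) / rate * 1000
  ibi_series(intervals, beat_times_ms = times, subject_id = subject_id)
}

#' Remove arrhythmic and movement artifacts from an IBI series
#'
#' Each interval is tested in order: values outside
#' `[min_ms, max_ms]` are removed as `out_of_range`; once five intervals
#' have been accepted, values deviating more than `max_rel_dev` from the
#' running median of the five most recently accepted intervals are removed
#' as `local_outlier`. Removed beats are deleted, shortening the series;
#' nothing is interpolated. Cleaning is idempotent: a second pass under the
#' same policy removes nothing.
#'
#' @param ibi an [ibi_series()] with at least 10 intervals.
#' @param policy a [cleaning_policy()].
#' @return list with components `ibi` (the cleaned [ibi_series()]) and
#'   `report` (class `artifact_report`: `n_input`, `n_removed`,
#'   `removal_reasons` named per removed position, `kept_fraction`,
#'   `low_quality` flag). Removal of more than `max_fraction` of beats is
#'   an error (recording unusable); more than `warn_fraction` sets
#'   `low_quality = TRUE` with a warning.
#' @export
clean_ibi <- function(ibi, policy = cleaning_policy()) {
  stopifnot(inherits(ibi, "ibi_series"), inherits(policy, "cleaning_policy"))
  x <- ibi$intervals_ms
  n <- length(x)
  if (n < 10L) stop("clean_ibi: need at least 10 intervals", call. = FALSE)

  keep <- logical(n)
  reasons <- character(0)
  reason_pos <- integer(0)
  accepted <- numeric(0)
  for (i in seq_len(n)) {
    v <- x[i]
    if (v < policy$min_ms || v > policy$max_ms) {
      reasons <- c(reasons, "out_of_range"); reason_pos <- c(reason_pos, i)
      next
    }
    if (length(accepted) >= 5L) {
      med <- stats::median(accepted[(length(accepted) - 4L):length(accepted)])
      if (abs(v - med) > policy$max_rel_dev * med) {
        reasons <- c(reasons, "local_outlier")
        reason_pos <- c(reason_pos, i)
        next
      }
    }
    keep[i] <- TRUE
    accepted <- c(accepted, v)
  }

  n_removed <- n - sum(keep)
  frac_removed <- n_removed / n
  if (frac_removed > policy$max_fraction)
    stop(sprintf("clean_ibi: %.0f%% of beats removed; recording unusable",
                 100 * frac_removed), call. = FALSE)
  low_quality <- frac_removed > policy$warn_fraction
  if (low_quality)
    warning(sprintf("clean_ibi: %.0f%% of beats removed; low quality",
                    100 * frac_removed))
  if (sum(keep) < 2L)
    stop("clean_ibi: fewer than 2 intervals survive cleaning",
         call. = FALSE)

  # deletion shortens the series: beat times are rebuilt by cumulative sum
  cleaned <- ibi_series(x[keep], subject_id = ibi$subject_id)
  report <- structure(
    list(n_input = n, n_removed = n_removed,
         removal_reasons = stats::setNames(reasons, reason_pos),
         kept_fraction = (n - n_removed) / n,
         low_quality = low_quality),
    class = "artifact_report")
  list(ibi = cleaned, report = report)
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("Artifact report: %d beats in, %d removed (%.1f%% kept)%s\n",
              x$n_input, x$n_removed, 100 * x$kept_fraction,
              if (x$low_quality) " [LOW QUALITY]" else ""))
  invisible(x)
}
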