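#' Spectral analysis configuration
#'
#' Parameters of the frequency-domain estimator: the unevenly sampled
#' tachogram (RR interval versus beat time) is resampled on an even grid
#' by cubic interpolation, linearly detrended, and its power spectral
#' density estimated by Welch's method (Hann-windowed overlapped segment
#' averaging). Band powers are trapezoidal integrals of the one-sided PSD
#' over LF (0.04-0.15 Hz), HF (0.15-0.40 Hz) and TP (0.0033-0.40 Hz);
#' band edges are inclusive-low / exclusive-high.
#'
#' @param resample_hz even resampling rate in Hz (default 4).
#' @param segment_s Welch segment length in seconds (default 120).
#' @param overlap_fraction fractional segment overlap (default 0.5).
#' @param vlf_lo,lf_lo,lf_hi,hf_hi band edges in Hz; must satisfy
#'   `0 < vlf_lo < lf_lo < lf_hi < hf_hi <= resample_hz / 2`.
#' @return a list of class `spectral_config`.
#' @export
spectral_config <- function(resample_hz = 4, segment_s = 120,
                            overlap_fraction = 0.5,
                            vlf_lo = 0.0033, lf_lo = 0.04,
                            lf_hi = 0.15, hf_hi = 0.40) {
  stopifnot(resample_hz > 0, segment_s > 0,
            overlap_fraction >= 0, overlap_fraction < 1,
            0 < vlf_lo, vlf_lo < lf_lo, lf_lo < lf_hi, lf_hi < hf_hi,
            hf_hi <= resample_hz / 2)
  structure(list(resample_hz = resample_hz, segment_s = segment_s,
                 overlap_fraction = overlap_fraction,
                 vlf_lo = vlf_lo, lf_lo = lf_lo, lf_hi = lf_hi,
                 hf_hi = hf_hi),
            class = "spectral_config")
}

#' Standard deviation of normal-to-normal intervals (SDNN)
#'
#' Sample standard deviation (denominator n - 1) of the intervals, in ms.
#' SDNN reflects total short-term variability.
#'
#' @param ibi an [ibi_series()] with at least 2 intervals.
#' @return SDNN in ms.
#' @export
sdnn <- function(ibi) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (length(ibi$intervals_ms) < 2L)
    stop("sdnn: need at least 2 intervals", call. = FALSE)
  stats::sd(ibi$intervals_ms)
}

#' Root mean square of successive differences (RMSSD)
#'
#' Square root of the mean squared successive interval difference (n - 1
#' differences for n intervals), in ms. RMSSD indexes vagally mediated
#' beat-to-beat variability.
#'
#' @param ibi an [ibi_series()] with at least 2 intervals.
#' @return RMSSD in ms.
#' @export
rmssd <- function(ibi) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (length(ibi$intervals_ms) < 2L)
    stop("rmssd: need at least 2 intervals", call. = FALSE)
  sqrt(mean(diff(ibi$intervals_ms)^2))
}

# Welch PSD of an evenly sampled series. Hann window, mean removed per
# segment, one-sided density scaled so that sum(psd) * df = variance.
welch_psd <- function(x, fs, segment_n, overlap_fraction) {
  n <- length(x)
  step <- max(1L, round(segment_n * (1 - overlap_fraction)))
  starts <- seq(1L, n - segment_n + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment_n) / (segment_n + 1)))
  scale <- fs * sum(w^2)
  nfreq <- segment_n %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + segment_n - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / scale
    acc <- acc + p[seq_len(nfreq)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when n even)
  dbl <- rep(2, nfreq); dbl[1L] <- 1
  if (segment_n %% 2L == 0L) dbl[nfreq] <- 1
  list(freq = (seq_len(nfreq) - 1L) * fs / segment_n, psd = psd * dbl)
}

# trapezoidal integral of psd over [lo, hi): the band is cut exactly at
# the edges by linear interpolation of the PSD
band_integral <- function(freq, psd, lo, hi) {
  f <- freq[freq >= lo & freq < hi]
  p <- psd[freq >= lo & freq < hi]
  if (length(f) < 2L) return(0)
  sum(diff(f) * (p[-1L] + p[-length(p)]) / 2)
}

#' Spectral band powers of an IBI series
#'
#' Resamples the tachogram at `cfg$resample_hz` by cubic interpolation
#' over the beat onset times, removes a linear trend, estimates the PSD by
#' Welch's method and integrates it over the LF, HF and TP bands.
#'
#' @param ibi a cleaned [ibi_series()] spanning at least 120 s.
#' @param cfg a [spectral_config()].
#' @return named list `lf_ms2`, `hf_ms2`, `tp_ms2` (ms^2) with attribute
#'   `short_recording = TRUE` when the span is below 300 s.
#' @export
band_powers <- function(ibi, cfg = spectral_config()) {
  stopifnot(inherits(ibi, "ibi_series"), inherits(cfg, "spectral_config"))
  n <- length(ibi$intervals_ms)
  t_onset <- ibi$beat_times_ms[seq_len(n)] / 1000  # s
  span <- t_onset[n] - t_onset[1L]
  if (span < cfg$segment_s)
    stop(sprintf("band_powers: series spans %.1f s; need >= %g s",
                 span, cfg$segment_s), call. = FALSE)

  grid <- seq(t_onset[1L], t_onset[n], by = 1 / cfg$resample_hz)
  rr <- stats::spline(t_onset, ibi$intervals_ms, xout = grid,
                      method = "fmm", ties = mean)$y
  # linear detrend
  rr <- stats::resid(stats::lm.fit(cbind(1, grid), rr))

  seg_n <- round(cfg$segment_s * cfg$resample_hz)
  if (length(rr) < seg_n)
    stop("band_powers: too few resampled points for one segment",
         call. = FALSE)
  sp <- welch_psd(rr, cfg$resample_hz, seg_n, cfg$overlap_fraction)

  out <- list(
    lf_ms2 = band_integral(sp$freq, sp$psd, cfg$lf_lo, cfg$lf_hi),
    hf_ms2 = band_integral(sp$freq, sp$psd, cfg$lf_hi, cfg$hf_hi),
    tp_ms2 = band_integral(sp$freq, sp$psd, cfg$vlf_lo, cfg$hf_hi))
  if (span < 300) attr(out, "short_recording") <- TRUE
  out
}

#' Compute the full set of short-term HRV indices
#'
#' Populates SDNN, RMSSD, the three band powers, the LF/HF ratio and the
#' natural-log transforms lnLF, lnHF, lnLF/HF, lnTP. The logs are taken
#' because raw band powers are strongly right-skewed. A non-positive band
#' power leaves the corresponding log undefined (`NA`) and is listed in
#' the `undefined` attribute; no epsilon is substituted.
#'
#' @param ibi a cleaned [ibi_series()].
#' @param cfg a [spectral_config()].
#' @return a list of class `hrv_indices` with the ten fields named by
#'   [hrv_index_names()].
#' @export
hrv_indices <- function(ibi, cfg = spectral_config()) {
  bp <- band_powers(ibi, cfg)
  lf <- bp$lf_ms2; hf <- bp$hf_ms2; tp <- bp$tp_ms2
  ratio <- if (hf > 0) lf / hf else NA_real_
  safe_log <- function(v) if (is.finite(v) && v > 0) log(v) else NA_real_
  out <- list(sdnn_ms = sdnn(ibi), rmssd_ms = rmssd(ibi),
              lf_ms2 = lf, hf_ms2 = hf, tp_ms2 = tp, lf_hf = ratio,
              ln_lf = safe_log(lf), ln_hf = safe_log(hf),
              ln_lf_hf = safe_log(ratio), ln_tp = safe_log(tp))
  undefined <- names(out)[vapply(out, function(v) is.na(v), logical(1))]
  attr(out, "undefined") <- undefined
  attr(out, "short_recording") <- isTRUE(attr(bp, "short_recording"))
  class(out) <- "hrv_indices"
  out
}

#' @export
print.hrv_indices <- function(x, ...) {
  cat("Short-term HRV indices:\n")
  for (nm in names(x))
    cat(sprintf("  %-9s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else sprintf("%.4f", x[[nm]])))
  invisible(x)
}
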