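# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic IBI generator
#'
#' The generator emulates a resting 5-minute tachogram as a mean RR level
#' plus one LF-band and one HF-band sinusoidal modulation and white
#' Gaussian beat-to-beat noise. Amplitudes are chosen so intervals stay
#' strictly positive: `mean_rr_ms - (lf_amp + hf_amp + 4 * noise_sd)`
#' must exceed 300 ms.
#'
#' @param mean_rr_ms mean interval (ms), default 800 (75 bpm).
#' @param lf_amp_ms,lf_freq_hz LF modulation amplitude (ms) and frequency
#'   (Hz, in (0.04, 0.15)); defaults 30 ms at 0.10 Hz.
#' @param hf_amp_ms,hf_freq_hz HF modulation amplitude and frequency
#'   (Hz, in (0.15, 0.40)); defaults 25 ms at 0.25 Hz (a typical resting
#'   respiratory frequency of 15 breaths/min).
#' @param noise_sd_ms white-noise SD (ms), default 10.
#' @param duration_s recording length (s), default 300.
#' @param seed RNG seed.
#' @return a list of class `synthetic_ibi_config`.
#' @export
synthetic_ibi_config <- function(mean_rr_ms = 800, lf_amp_ms = 30,
                                 lf_freq_hz = 0.10, hf_amp_ms = 25,
                                 hf_freq_hz = 0.25, noise_sd_ms = 10,
                                 duration_s = 300, seed = 1L) {
  stopifnot(lf_amp_ms >= 0, hf_amp_ms >= 0, noise_sd_ms >= 0,
            duration_s > 0,
            lf_freq_hz > 0.04, lf_freq_hz < 0.15,
            hf_freq_hz > 0.15, hf_freq_hz < 0.40)
  if (mean_rr_ms - (lf_amp_ms + hf_amp_ms + 4 * noise_sd_ms) <= 300)
    stop("synthetic_ibi_config: modulation too large for positive intervals",
         call. = FALSE)
  structure(list(mean_rr_ms = mean_rr_ms, lf_amp_ms = lf_amp_ms,
                 lf_freq_hz = lf_freq_hz, hf_amp_ms = hf_amp_ms,
                 hf_freq_hz = hf_freq_hz, noise_sd_ms = noise_sd_ms,
                 duration_s = duration_s, seed = as.integer(seed)),
            class = "synthetic_ibi_config")
}

#' Generate a synthetic interbeat-interval series
#'
#' Beats are placed by forward iteration of the instantaneous RR
#' function (an integral-pulse-style surrogate): the next beat falls at
#' `t + RR(t)`, where `RR(t) = mean + lf_amp sin(2 pi f_lf t) +
#' hf_amp sin(2 pi f_hf t) + N(0, noise_sd)`. This gives exact knowledge
#' of the spectral content and beat times, which downstream tests use as
#' ground truth. Deterministic for a given seed.
#'
#' @param cfg a [synthetic_ibi_config()].
#' @return an [ibi_series()].
#' @export
gen_ibi <- function(cfg = synthetic_ibi_config()) {
  stopifnot(inherits(cfg, "synthetic_ibi_config"))
  with_seed(cfg$seed, {
    t_ms <- 0
    intervals <- numeric(0)
    end_ms <- cfg$duration_s * 1000
    while (t_ms < end_ms) {
      t_s <- t_ms / 1000
      rr <- cfg$mean_rr_ms +
        cfg$lf_amp_ms * sin(2 * pi * cfg$lf_freq_hz * t_s) +
        cfg$hf_amp_ms * sin(2 * pi * cfg$hf_freq_hz * t_s) +
        stats::rnorm(1, 0, cfg$noise_sd_ms)
      intervals <- c(intervals, rr)
      t_ms <- t_ms + rr
    }
    ibi_series(intervals, subject_id = "synthetic")
  })
}

#' Render an ECG waveform from an IBI series
#'
#' Places a fixed QRS-like template (dominant R deflection of about 80 ms
#' total width with small Q and S dips) at every beat time over white
#' baseline noise. The R apex coincides with the beat time to within one
#' sample, so the output doubles as ground truth for R-peak detection.
#'
#' @param ibi an [ibi_series()]; every interval must exceed the template
#'   width (80 ms).
#' @param rate sampling rate in Hz, >= 100.
#' @param noise_sd baseline noise SD in the template's amplitude units
#'   (R apex = 1), default 0.02.
#' @param seed RNG seed for the baseline noise.
#' @return an [ecg_record()].
#' @export
gen_ecg_from_ibi <- function(ibi, rate = 2048, noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (rate < 100)
    stop("gen_ecg_from_ibi: rate must be >= 100 Hz", call. = FALSE)
  if (any(ibi$intervals_ms < 80))
    stop("gen_ecg_from_ibi: interval shorter than QRS template width",
         call. = FALSE)
  beat_ms <- ibi$beat_times_ms
  n <- ceiling((beat_ms[length(beat_ms)] + 500) / 1000 * rate)
  # QRS template on a +/- 40 ms support: R apex 1.0, Q and S dips
  half_ms <- 40
  k <- round(half_ms / 1000 * rate)
  tt <- (-k:k) / rate * 1000  # ms relative to apex
  template <- exp(-tt^2 / (2 * 8^2)) -
    0.15 * exp(-(tt + 26)^2 / (2 * 4^2)) -
    0.20 * exp(-(tt - 26)^2 / (2 * 4^2))
  x <- with_seed(seed, stats::rnorm(n, 0, noise_sd))
  centers <- round(beat_ms / 1000 * rate) + 1L
  for (c0 in centers) {
    lo <- c0 - k; hi <- c0 + k
    sel <- lo:hi >= 1L & lo:hi <= n
    x[(lo:hi)[sel]] <- x[(lo:hi)[sel]] + template[sel]
  }
  ecg_record(x, rate, lead_label = "II", subject_id = ibi$subject_id)
}

#' Configuration for the synthetic cohort generator
#'
#' Each HRV index is modelled linearly in age with a sex offset:
#' `index = intercept + slope_per_decade * (age - 20) / 10 +
#' female_offset * [sex == female] + N(0, resid_sd)`. Defaults emulate
#' the structure reported for healthy East-Asian adults: indices decline
#' with age, females show higher vagally mediated indices (RMSSD, lnHF)
#' and a lower LF/HF balance, and the all-ages means and SDs sit near the
#' published Taiwanese reference cells. The clinical (MDD) group is
#' shifted down by `group_offset_sd` residual SDs, and its symptom scores
#' are generated from the subject's lnLF deviation so that
#' `cor(score, z)` approaches `symptom_coupling` (negative: more severe
#' symptoms, lower HRV).
#'
#' @param index_params data frame with rownames =
#'   [reported_index_names()] and columns `intercept` (value at age 20),
#'   `slope_per_decade`, `female_offset`, `resid_sd`.
#' @param group_offset_sd MDD shift in residual-SD units, default -0.55.
#' @param symptom_coupling target correlation between symptom scores and
#'   index z, in \[-1, 0\]; default -0.2.
#' @param n_per_stratum subjects per age decade (scalar or length-5
#'   vector), default 30; must be >= 2.
#' @param seed RNG seed.
#' @return a list of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(index_params = default_index_params(),
                                    group_offset_sd = -0.55,
                                    symptom_coupling = -0.2,
                                    n_per_stratum = 30, seed = 1L) {
  stopifnot(is.data.frame(index_params),
            all(c("intercept", "slope_per_decade", "female_offset",
                  "resid_sd") %in% names(index_params)),
            all(reported_index_names() %in% rownames(index_params)),
            all(index_params$resid_sd > 0),
            symptom_coupling >= -1, symptom_coupling <= 0)
  if (length(n_per_stratum) == 1L) n_per_stratum <- rep(n_per_stratum, 5L)
  stopifnot(length(n_per_stratum) == 5L)
  if (any(n_per_stratum < 2L))
    stop("synthetic_cohort_config: n_per_stratum must be >= 2",
         call. = FALSE)
  structure(list(index_params = index_params,
                 group_offset_sd = group_offset_sd,
                 symptom_coupling = symptom_coupling,
                 n_per_stratum = as.integer(n_per_stratum),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

#' @rdname synthetic_cohort_config
#' @export
default_index_params <- function() {
  p <- data.frame(
    intercept        = c(52,  42,  5.5,  5.6,  0.30, 6.90),
    slope_per_decade = c(-5,  -5, -0.35, -0.40, 0.00, -0.30),
    female_offset    = c(0,    5, -0.10, 0.40, -0.50, 0.00),
    resid_sd         = c(14,  15,  1.10, 1.20, 1.00, 0.85))
  rownames(p) <- reported_index_names()
  p
}

#' Generate a synthetic stratified cohort
#'
#' Draws `n_per_stratum` subjects per age decade (ages uniform within the
#' bin, sexes balanced), with index values from the linear age/sex model
#' of [synthetic_cohort_config()]. For `group = "MDD"` all indices are
#' shifted by `group_offset_sd` residual SDs and BDI-II / BAI totals are
#' generated from the subject's lnLF residual z so that symptom severity
#' correlates negatively with HRV (magnitudes follow the published MDD
#' score distributions, BDI-II about 32 +/- 10); healthy controls receive
#' scores inside the normative screening range (BDI-II < 14, BAI < 8).
#' Deterministic for a given seed.
#'
#' @param cfg a [synthetic_cohort_config()].
#' @param group `"HC"` or `"MDD"`.
#' @return a cohort data frame (see [as_cohort_table()]) with the six
#'   reported index columns.
#' @export
gen_cohort <- function(cfg = synthetic_cohort_config(),
                       group = c("HC", "MDD")) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  group <- match.arg(group)
  scheme <- age_decades()
  p <- cfg$index_params
  idx_names <- reported_index_names()

  with_seed(cfg$seed, {
    rows <- list()
    sid <- 0L
    for (b in seq_len(nrow(scheme))) {
      n <- cfg$n_per_stratum[b]
      n_male <- n %/% 2L
      sexes <- c(rep("male", n_male), rep("female", n - n_male))
      ages <- stats::runif(n, scheme$age_lo[b], scheme$age_hi[b])
      for (i in seq_len(n)) {
        sid <- sid + 1L
        resid_z <- stats::rnorm(length(idx_names))
        names(resid_z) <- idx_names
        vals <- p[idx_names, "intercept"] +
          p[idx_names, "slope_per_decade"] * (ages[i] - 20) / 10 +
          p[idx_names, "female_offset"] * (sexes[i] == "female") +
          p[idx_names, "resid_sd"] * resid_z
        if (group == "MDD")
          vals <- vals + cfg$group_offset_sd * p[idx_names, "resid_sd"]
        names(vals) <- idx_names

        if (group == "HC") {
          bdi <- min(stats::rpois(1, 4.4), 13L)
          bai <- min(stats::rpois(1, 2.0), 7L)
        } else {
          cpl <- cfg$symptom_coupling
          mix <- function(z) cpl * z + sqrt(1 - cpl^2) * stats::rnorm(1)
          bdi <- round(32 + 10 * mix(resid_z[["ln_lf"]]))
          bdi <- min(max(bdi, 15L), 63L)
          bai <- round(22 + 9 * mix(resid_z[["ln_lf"]]))
          bai <- min(max(bai, 9L), 63L)
        }
        bdi_cog <- round(0.75 * bdi)
        bai_cog <- round(0.60 * bai)

        rows[[sid]] <- data.frame(
          subject_id = sprintf("%s%04d", group, sid),
          age = ages[i], sex = sexes[i], group = group,
          bdi_total = bdi, bdi_cognitive = bdi_cog,
          bdi_somatic = bdi - bdi_cog,
          bai_total = bai, bai_cognitive = bai_cog,
          bai_somatic = bai - bai_cog,
          as.data.frame(as.list(vals)))
      }
    }
    as_cohort_table(do.call(rbind, rows))
  })
}

#' Published screening ledgers
#'
#' Exclusion-category counts of the normative study's recruitment:
#' healthy controls (356 recruited; excluded for age under 20, age over
#' 70, over-threshold questionnaire scores, physical illness; removed
#' for ECG measurement issues or arrhythmia/artifacts) and the clinical
#' group (422 referred; additionally excluded for a non-MDD primary
#' diagnosis or daytime sleepiness, removed for missing data).
#'
#' @return named list of counts usable with [gen_screening_roster()].
#' @export
hc_screening_ledger <- function() {
  list(recruited = 356, age_under = 1, age_over = 4, scores = 14,
       illness = 7, measurement = 14, arrhythmia = 5)
}

#' @rdname hc_screening_ledger
#' @export
mdd_screening_ledger <- function() {
  list(recruited = 422, age_under = 7, age_over = 3, scores = 97,
       not_mdd = 2, illness = 8, sleepiness = 1,
       measurement = 12, missing = 14, arrhythmia = 6)
}

#' Generate a screening roster from an exclusion ledger
#'
#' Emits one record per recruited participant; each excluded record
#' carries exactly the attribute its ledger category names (an age
#' violation, an over/under-threshold score, an illness or diagnosis
#' flag, or a recording-quality flag), and all remaining records are
#' fully eligible. Applying [screen_roster()] to the result reproduces
#' the ledger's survivor count exactly.
#'
#' @param ledger named list of non-negative counts: `recruited` plus any
#'   of `age_under`, `age_over`, `scores`, `illness`, `not_mdd`,
#'   `sleepiness`, `measurement`, `missing`, `arrhythmia`.
#' @param group `"HC"` or `"MDD"`.
#' @return list with `roster` (data frame) and `expected_survivors`.
#' @export
gen_screening_roster <- function(ledger, group = c("HC", "MDD")) {
  group <- match.arg(group)
  counts <- ledger
  counts$recruited <- NULL
  counts <- lapply(counts, as.integer)
  if (any(unlist(counts) < 0) || ledger$recruited < 0)
    stop("gen_screening_roster: negative count", call. = FALSE)
  n_excl <- sum(unlist(counts))
  if (n_excl > ledger$recruited)
    stop("gen_screening_roster: exclusions exceed recruitment",
         call. = FALSE)

  is_mdd <- group == "MDD"
  base <- function() list(
    age = 40,
    bdi_total = if (is_mdd) 30 else 5,
    bai_total = if (is_mdd) 20 else 3,
    severe_illness = FALSE,
    mdd_diagnosis = is_mdd,
    daytime_sleepiness = FALSE,
    measurement_issue = FALSE, missing_data = FALSE, arrhythmia = FALSE)
  tweak <- function(category) {
    r <- base()
    switch(category,
      age_under   = r$age <- 19,
      age_over    = r$age <- 75,
      scores      = if (is_mdd) { r$bdi_total <- 5; r$bai_total <- 3 }
                    else { r$bdi_total <- 20; r$bai_total <- 12 },
      illness     = r$severe_illness <- TRUE,
      not_mdd     = r$mdd_diagnosis <- FALSE,
      sleepiness  = r$daytime_sleepiness <- TRUE,
      measurement = r$measurement_issue <- TRUE,
      missing     = r$missing_data <- TRUE,
      arrhythmia  = r$arrhythmia <- TRUE,
      stop("gen_screening_roster: unknown category ", category,
           call. = FALSE))
    r
  }
  recs <- list()
  for (category in names(counts))
    for (i in seq_len(counts[[category]]))
      recs[[length(recs) + 1L]] <- tweak(category)
  for (i in seq_len(ledger$recruited - n_excl))
    recs[[length(recs) + 1L]] <- base()
  roster <- do.call(rbind, lapply(recs, as.data.frame))
  roster <- cbind(subject_id = sprintf("%s-R%04d", group,
                                       seq_len(nrow(roster))), roster)
  list(roster = roster, expected_survivors = ledger$recruited - n_excl)
}

#' Apply screening and quality filters to a roster
#'
#' Runs [screen_participant()] on every record and then removes records
#' with recording-quality problems (measurement issues, missing data,
#' arrhythmia/artifacts), mirroring the two-stage exclusion of a
#' normative recruitment: enrolment screening first, data-quality review
#' second.
#'
#' @param roster data frame as produced by [gen_screening_roster()].
#' @param group `"HC"` or `"MDD"`.
#' @return list with `n_survivors`, `survivors` (data frame) and
#'   `reasons` (table of exclusion reasons).
#' @export
screen_roster <- function(roster, group = c("HC", "MDD")) {
  group <- match.arg(group)
  reasons <- character(nrow(roster))
  for (i in seq_len(nrow(roster))) {
    s <- screen_participant(roster[i, ], group)
    if (!s$eligible) {
      reasons[i] <- s$reason
    } else if (isTRUE(roster$measurement_issue[i])) {
      reasons[i] <- "measurement_issue"
    } else if (isTRUE(roster$missing_data[i])) {
      reasons[i] <- "missing_data"
    } else if (isTRUE(roster$arrhythmia[i])) {
      reasons[i] <- "arrhythmia"
    }
  }
  keep <- reasons == ""
  list(n_survivors = sum(keep),
       survivors = roster[keep, , drop = FALSE],
       reasons = table(reasons[!keep]))
}
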