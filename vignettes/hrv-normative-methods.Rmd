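---
title: "Methods: short-term HRV indices, normative tables and Z-scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: short-term HRV indices, normative tables and Z-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvnorm)
```

This vignette documents the models, conventions and numerical choices
behind `hrvnorm`, in the order the pipeline applies them: R-peak
detection, artifact removal, index computation, normative-table
construction, Z-score standardization, and the cohort statistics.

## Signal model and R-peak detection

The package assumes a single-lead resting ECG (the reference acquisition
protocol is Lead II at 2048 Hz, five minutes seated with eyes closed) or
a precomputed interbeat-interval (IBI) export. `detect_r_peaks()` is a
deterministic Pan–Tompkins-style detector:

1. zero-phase band-pass 5–30 Hz (2nd-order Butterworth, forward–backward),
   isolating QRS energy from baseline wander and T waves;
2. differentiate, square, and integrate over a 150 ms moving window;
3. threshold at 20% of the 99th percentile of the integrated energy;
4. one fiducial point per supra-threshold run, refined to the local
   maximum of the band-passed signal within ±50 ms;
5. a 250 ms refractory period (no physiological RR is shorter); when two
   candidates collide, the larger amplitude wins.

The fixed-quantile threshold is deliberately simple: it is deterministic,
has no warm-up transient, and on template-based test signals recovers
better than 99% of beats to within ±10 ms with a mean timing error near
0.1 ms at 2048 Hz. It has no claim to clinical robustness against
electrode motion or morphology change; recordings that defeat it surface
as artifact-heavy interval series and fail the quality gates below
rather than passing silently.

## Artifact removal

`clean_ibi()` removes (never interpolates) intervals that fail either of
two gates:

- **absolute range**: outside \[300, 2000\] ms (200–30 bpm);
- **local consistency**: once five intervals have been accepted,
  deviation of more than 20% from the running median of the five most
  recently accepted intervals.

These thresholds are the common practice in short-term HRV cleaning, not
values fixed by any reference dataset, and are exposed in
`cleaning_policy()`. Deletion is chosen over interpolation because
interpolation manufactures spectral power at exactly the frequencies the
analysis integrates; after deletion, beat times are rebuilt by cumulative
sum, which compresses the time axis slightly — acceptable at the removal
rates the quality gates allow. Using only *accepted* predecessors in the
running median makes cleaning exactly idempotent: a second pass removes
nothing. Removal above 20% of beats flags the recording `low_quality`
(replacing the manual waveform review a human scorer would perform);
above 50% the recording is rejected outright.

## Index computation

Time domain, over the cleaned intervals in ms: SDNN (sample SD,
denominator n − 1) and RMSSD (root mean square of the n − 1 successive
differences). Both have closed forms, and the implementation is tested
against independent two-pass oracles at 1e−9 relative tolerance.

Frequency domain (`band_powers()`): the interval-versus-onset-time
tachogram is resampled at 4 Hz by cubic spline, linearly detrended, and
the PSD estimated by Welch's method — Hann window, 120 s segments, 50%
overlap, per-segment mean removal, one-sided density normalized so its
integral equals the signal variance. Band powers are trapezoidal
integrals over LF 0.04–0.15 Hz, HF 0.15–0.40 Hz and TP 0.0033–0.40 Hz
(edges inclusive-low/exclusive-high, so no mass is counted twice). The
Welch estimator is implemented in the package directly on `stats::fft()`,
as no installed estimator offered the required segment-averaged one-sided
form. These are the conventional Task-Force-style choices for 5-minute
recordings; all are adjustable through `spectral_config()`. A 300 s
recording yields four segments — enough averaging to keep a pure
sinusoidal modulation's integrated band power within a few percent of its
analytic variance A²/2 (the Parseval tests in the suite run at 0.4%
error), while 0.00833 Hz resolution still separates the LF floor at
0.04 Hz cleanly from the 0.0033 Hz TP floor.

Conventions worth stating:

- Recordings shorter than 120 s are errors; 120–300 s carry a
  `short_recording` flag. The target protocol is five minutes.
- The log-transformed indices (lnLF, lnHF, lnLF/HF, lnTP) are reported
  because raw powers are strongly right-skewed. Published tables in this
  literature sometimes print these with PSD units (ms²/Hz); the
  band-integrated quantity is ms², and that is what this package reports.
- A non-positive band power leaves its log `NA` and listed under the
  `undefined` attribute. No epsilon is substituted: inventing a floor
  value would silently bias downstream norms. Norm construction simply
  skips undefined cells.
- TP integrates the full printed band including the 0.0033–0.04 Hz VLF
  mass, so TP ≥ LF and TP ≥ HF by construction.

## Normative tables and Z-scores

`build_norm_table()` computes, for every (age bin × sex group × index)
cell, the sample mean μ, sample SD σ (denominator n − 1; the customary
estimator in the normative-database literature) and n. The reference
stratification is the five adult decades \[20,30) … \[60,70), half-open
so that age 30 falls in \[30,40). Cells with n < 2 or σ = 0 are unusable
as norms and are omitted with a warning; strata simply absent from the
cohort are skipped silently.

`z_score()` is the exact standardization z = (x − μ)/σ, and
`z_report()` resolves the norm entry by the fallback chain

(age-bin, sex) → (age-bin, pooled) → (all-ages, sex) → (all-ages, pooled),

recording which stratum was used. The deviation flag is strict:
|z| > 1.96, i.e. outside the central 95% of a normal reference; a value
at exactly 1.96 is *not* deviant. The threshold is configurable.

`taiwan_reference()` embeds the published healthy-control reference cells
for Taiwanese adults aged 20–70: the pooled-sex all-ages means and SDs of
the six reported indices (n = 311) and the male/female all-ages cells
(n = 137/174). Age-stratified reference cells were not published, so only
all-ages strata are embedded and age-specific lookups fall back as above;
we chose not to fabricate decade cells from the printed aggregates.
`cohort_z_summary()` standardizes a whole cohort and tabulates mean ± SD
of z and |z| per age decade. By default it standardizes every subject
against pooled-sex entries (`use_sex_strata = FALSE`), since
cross-validation summaries of this shape are conventionally computed on
age strata alone; sex-specific standardization is one switch away.

## Cohort statistics

The validation battery follows the conventions of the normative-HRV
literature:

- `chi_square_2x2()`: Pearson χ² **without** continuity correction —
  the uncorrected statistic is what published sex-distribution
  comparisons report (the embedded 137/174 vs 66/206 table reproduces
  25.030 only without correction).
- `student_t()`: pooled-variance two-sample t, df = n₁ + n₂ − 2.
- `ancova_group()`: ordinary least squares `y ~ group + covariate`; the
  group term is tested by its extra sum of squares given the covariate
  (type II), with partial η² = SS_group/(SS_group + SS_error). With a
  covariate orthogonal to the group factor this is one-way ANOVA up to
  the error degree of freedom spent on the covariate.
- `pearson()`: product-moment r with the two-sided p from
  t = r√((n−2)/(1−r²)).
- All p-values are two-sided; no multiple-testing correction is applied,
  matching per-cell reporting practice in this literature. That is a
  known limitation, not an endorsement: users scanning many cells should
  adjust externally (e.g. `p.adjust`).
- Group factors are ordered HC before MDD, fixing the sign convention of
  t statistics.

Screening (`screen_participant()`) applies the enrolment rules in order
and reports the first failure. The healthy-control rules are BDI-II < 14
and BAI < 8; the clinical rules are BDI-II > 14 and BAI > 8 — read
literally, scores of exactly 14/8 satisfy neither, and the screen
surfaces them as `excluded(boundary)` rather than silently assigning a
side. Severity bands (`classify_severity()`) place BDI-II 13 in the
normal range, per the standard convention. One further published
inconsistency is worth noting: the clinical male/female counts appear
both as 58/163 and 66/206 in different places of the source material;
the package embeds 66/206, the version whose χ² reproduces the printed
25.030.

## The synthetic-data generators

The generators are first-class, tested code; they define the conditions
under which the pipeline is validated.

`gen_ibi()` places beats by forward iteration of an instantaneous RR
function (an integral-pulse-style surrogate): RR(t) = mean +
A_LF sin(2πf_LF t) + A_HF sin(2πf_HF t) + N(0, σ). Defaults: 800 ms mean
(75 bpm), 30 ms at 0.10 Hz, 25 ms at 0.25 Hz (15 breaths/min), 10 ms
noise, 300 s. This gives exact ground truth for beat times and band
variances. `gen_ecg_from_ibi()` renders a fixed ~80 ms QRS-like template
(R apex normalized to 1, small Q/S dips) at each beat time over white
baseline noise (SD 0.02 by default), with the apex within one sample of
the beat time.

`gen_cohort()` draws each index from a linear age/sex model:
intercept (value at age 20) + slope·(age−20)/10 + female offset +
Gaussian residual, ages uniform within each decade and sexes balanced.
The default parameters (see `default_index_params()`) were set once to
make the all-ages means and SDs land near the embedded reference cells
while reproducing the qualitative structure reported for healthy adults —
indices decline with age, females show higher RMSSD/lnHF and lower
LF/HF balance; no published effect sizes exist for the slopes, so the
magnitudes (e.g. −5 ms SDNN per decade) are the package's own realistic
choices. The clinical group is shifted by −0.55 residual SDs (the
standardized contrast implied by the published SDNN group means), and its
BDI-II/BAI totals are generated *from* the subject's lnLF residual with
coupling −0.2 plus independent noise, centred at the published clinical
score level (BDI-II ≈ 32 ± 10) — generating scores from HRV rather than
vice versa sets the correlation sign directly.

`gen_screening_roster()` materializes an exclusion ledger as individual
records, each carrying exactly the attribute its category names, so that
`screen_roster()` reproduces the ledger's survivor count exactly (311 of
356 recruited controls; 272 of 422 referred patients, with the published
category counts).

What the generators deliberately do **not** model: realistic ECG
morphology beyond the QRS template (no P/T waves, no electrode artifact),
respiratory-cardiac coupling beyond a fixed HF tone, circadian or
posture effects, unbalanced stratum sampling (available via per-stratum
overrides but not the default), and any antidepressant effect on HRV.
Passing tests therefore demonstrate internal consistency — detector
accuracy on clean morphology, Parseval closure, parameter recovery,
correlation-sign recovery — not field performance on clinical ECG.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to be
statistically meaningful yet quick: 300 s series for spectral oracles,
~300 rendered beats for detector closure, 30 subjects per stratum × 10
seeds for parameter recovery (300 cells), and 100 seeds × 272 subjects
for correlation-sign recovery. Every generator consumes an explicit seed
and restores the caller's RNG state, so identical configurations produce
byte-identical outputs; pipeline reports embed input checksums and a
configuration hash so a rerun can be verified byte-for-byte
(timestamps are deliberately absent).
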