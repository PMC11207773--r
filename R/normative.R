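#' Reference age stratification
#'
#' The canonical decade scheme for adult norms: five half-open bins
#' \[20,30), \[30,40), \[40,50), \[50,60), \[60,70). Half-open bins mean
#' age 30 falls in \[30, 40).
#'
#' @return data frame with columns `age_lo`, `age_hi`.
#' @export
age_decades <- function() {
  data.frame(age_lo = seq(20, 60, by = 10),
             age_hi = seq(30, 70, by = 10))
}

#' Build a stratified normative table from a healthy cohort
#'
#' For every (age bin x sex group x index) cell, computes the sample mean,
#' sample standard deviation (denominator n - 1) and n over rows with a
#' defined value. Cells with n < 2 or zero variance are omitted with a
#' warning, since a usable norm needs sigma > 0.
#'
#' @param cohort a cohort data frame (see [as_cohort_table()]) carrying
#'   the index columns to normalize.
#' @param scheme age bins as a data frame of `age_lo`, `age_hi`
#'   (default [age_decades()]); bins must cover each row exactly once.
#' @param by_sex which sex strata to emit: any of `"pooled"`, `"male"`,
#'   `"female"` (default all three).
#' @param indices index columns to include (default the six reported
#'   indices present in `cohort`).
#' @param provenance provenance string stored on the table.
#' @return a [norm_table()].
#' @export
build_norm_table <- function(cohort, scheme = age_decades(),
                             by_sex = c("pooled", "male", "female"),
                             indices = NULL, provenance = "built from cohort") {
  cohort <- as_cohort_table(cohort)
  if (nrow(cohort) == 0L)
    stop("build_norm_table: empty cohort", call. = FALSE)
  if (is.null(indices))
    indices <- intersect(reported_index_names(), names(cohort))
  if (length(indices) == 0L)
    stop("build_norm_table: cohort has no index columns", call. = FALSE)
  by_sex <- match.arg(by_sex, several.ok = TRUE)

  bin_of <- function(age) {
    hit <- which(age >= scheme$age_lo & age < scheme$age_hi)
    if (length(hit) != 1L)
      stop(sprintf("build_norm_table: age %.1f not covered by exactly one bin",
                   age), call. = FALSE)
    hit
  }
  bins <- vapply(cohort$age, bin_of, integer(1))

  rows <- list()
  skipped <- character(0)
  for (b in seq_len(nrow(scheme))) {
    for (sx in by_sex) {
      in_stratum <- bins == b & (sx == "pooled" | cohort$sex == sx)
      for (idx in indices) {
        v <- cohort[[idx]][in_stratum]
        v <- v[is.finite(v)]
        if (length(v) == 0L) next  # stratum simply absent from the cohort
        if (length(v) < 2L || stats::sd(v) == 0) {
          skipped <- c(skipped, sprintf("[%d,%d) %s %s",
                                        scheme$age_lo[b], scheme$age_hi[b],
                                        sx, idx))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          stratum_age_lo = scheme$age_lo[b],
          stratum_age_hi = scheme$age_hi[b],
          sex = sx, index_name = idx,
          mean = mean(v), sd = stats::sd(v), n = length(v))
      }
    }
  }
  if (length(skipped) > 0L)
    warning("build_norm_table: omitted degenerate strata (n < 2 or sd = 0): ",
            paste(skipped, collapse = "; "))
  if (length(rows) == 0L)
    stop("build_norm_table: no usable strata", call. = FALSE)
  norm_table(do.call(rbind, rows), provenance = provenance)
}

#' Embedded Taiwanese adult reference norms
#'
#' The published all-ages healthy-control reference cells for Taiwanese
#' adults aged 20-70: pooled-sex means and SDs for the six reported
#' indices (n = 311) plus the male (n = 137) and female (n = 174)
#' all-ages cells. Age-stratified reference cells were not published, so
#' age-specific lookups against this table fall back to the all-ages
#' sex or pooled entry (see [z_report()]).
#'
#' @return a [norm_table()] whose strata all span \[20, 70).
#' @export
taiwan_reference <- function() {
  idx <- reported_index_names()
  cell <- function(sex, means, sds, n)
    data.frame(stratum_age_lo = 20, stratum_age_hi = 70, sex = sex,
               index_name = idx, mean = means, sd = sds, n = n)
  entries <- rbind(
    cell("pooled",
         means = c(41.95, 31.41, 4.68, 4.63, 0.06, 6.14),
         sds   = c(16.26, 16.06, 1.15, 1.25, 1.06, 0.88), n = 311),
    cell("male",
         means = c(41.50, 28.17, 4.76, 4.41, 0.35, 6.13),
         sds   = c(16.80, 13.83, 1.26, 1.29, 1.05, 0.95), n = 137),
    cell("female",
         means = c(42.30, 33.96, 4.63, 4.80, -0.17, 6.15),
         sds   = c(15.87, 17.23, 1.04, 1.19, 1.01, 0.82), n = 174))
  norm_table(entries,
             provenance = paste("Taiwan adult HRV reference, healthy",
                                "controls aged 20-70; published all-ages",
                                "cells (pooled n=311, male n=137,",
                                "female n=174)"))
}

#' Z-score of one index value against a norm entry
#'
#' @param x index value.
#' @param mu stratum mean.
#' @param sigma stratum standard deviation, > 0.
#' @return `(x - mu) / sigma`; `NA` when `x` is undefined.
#' @export
z_score <- function(x, mu, sigma) {
  if (!is.finite(sigma) || sigma <= 0)
    stop("z_score: sigma must be positive", call. = FALSE)
  if (!is.finite(x)) return(NA_real_)
  (x - mu) / sigma
}

# resolve the norm entry for (age, sex, index) with the fallback chain
# (age-bin, sex) -> (age-bin, pooled) -> (all-ages, sex) -> (all-ages, pooled)
lookup_stratum <- function(table, age, sex, index_name) {
  d <- as.data.frame(table)
  d <- d[d$index_name == index_name &
           age >= d$stratum_age_lo & age < d$stratum_age_hi &
           d$sex %in% c(sex, "pooled"), , drop = FALSE]
  if (nrow(d) == 0L) return(NULL)
  # narrowest covering bin wins; within a bin the subject's own sex
  # stratum is preferred over the pooled one
  ord <- order(d$stratum_age_hi - d$stratum_age_lo, d$sex == "pooled")
  d[ord[1L], , drop = FALSE]
}

#' Z-score report for one subject against a normative table
#'
#' Standardizes each index as `z = (x - mu) / sigma` against the norm
#' entry matched to the subject's age and sex. Lookup prefers the
#' (age-bin, sex) entry, then (age-bin, pooled), then the all-ages sex
#' and pooled entries. An index is flagged deviant when `|z| > threshold`
#' (strictly), i.e. the value falls outside the mean +/- 1.96 SD range of
#' the reference stratum at the default threshold.
#'
#' @param indices an `hrv_indices` object or named list/vector of index
#'   values.
#' @param age subject age in years.
#' @param sex `"male"` or `"female"`.
#' @param table a [norm_table()].
#' @param threshold deviation flag threshold on `|z|` (default 1.96).
#' @return a data frame of class `z_report` with columns `index`, `x`,
#'   `z`, `abs_z`, `deviant`, `stratum_age_lo`, `stratum_age_hi`,
#'   `stratum_sex`; undefined indices are listed in the
#'   `undefined_indices` attribute and carry `NA` scores.
#' @export
z_report <- function(indices, age, sex, table = taiwan_reference(),
                     threshold = 1.96) {
  stopifnot(sex %in% c("male", "female"), threshold > 0)
  vals <- unlist(unclass(indices)[names(unclass(indices)) %in%
                                    hrv_index_names()])
  if (length(vals) == 0L) vals <- unlist(indices)
  index_names <- intersect(unique(as.data.frame(table)$index_name),
                           names(vals))
  if (length(index_names) == 0L)
    stop("z_report: no indices in common between subject and table",
         call. = FALSE)
  rows <- lapply(index_names, function(idx) {
    entry <- lookup_stratum(table, age, sex, idx)
    if (is.null(entry))
      stop(sprintf("z_report: no norm stratum covers (age %.1f, %s) for %s",
                   age, sex, idx), call. = FALSE)
    z <- z_score(vals[[idx]], entry$mean, entry$sd)
    data.frame(index = idx, x = vals[[idx]], z = z, abs_z = abs(z),
               deviant = is.finite(z) && abs(z) > threshold,
               stratum_age_lo = entry$stratum_age_lo,
               stratum_age_hi = entry$stratum_age_hi,
               stratum_sex = entry$sex)
  })
  out <- do.call(rbind, rows)
  attr(out, "undefined_indices") <- out$index[!is.finite(out$z)]
  attr(out, "threshold") <- threshold
  class(out) <- c("z_report", "data.frame")
  out
}

#' Stratified Z-score summary of a cohort
#'
#' Standardizes every subject in a cohort against a normative table and
#' summarizes, per age group and index, the mean and SD of z and of |z|,
#' together with stratum n and male/female counts. This is the matrix
#' used to cross-validate a normative database on a clinical sample.
#'
#' @param cohort a cohort data frame with demographics and index columns.
#' @param table a [norm_table()].
#' @param scheme age bins (default [age_decades()]).
#' @param use_sex_strata if FALSE (default) subjects are standardized
#'   against pooled-sex entries regardless of their sex; if TRUE the
#'   subject's own sex stratum is preferred.
#' @param threshold deviation threshold passed to [z_report()].
#' @return a data frame of class `cohort_z_summary`: one row per
#'   (age group x index) with `mean_z`, `sd_z`, `mean_abs_z`, `sd_abs_z`,
#'   `n`, `n_male`, `n_female`; empty strata are absent.
#' @export
cohort_z_summary <- function(cohort, table = taiwan_reference(),
                             scheme = age_decades(),
                             use_sex_strata = FALSE, threshold = 1.96) {
  cohort <- as_cohort_table(cohort)
  indices <- intersect(unique(as.data.frame(table)$index_name),
                       names(cohort))
  if (length(indices) == 0L)
    stop("cohort_z_summary: no indices in common", call. = FALSE)

  zcols <- matrix(NA_real_, nrow(cohort), length(indices),
                  dimnames = list(NULL, indices))
  for (i in seq_len(nrow(cohort))) {
    # pooled-only lookup uses a sex label matching no sex-specific stratum
    sex_for_lookup <- if (use_sex_strata) cohort$sex[i] else "pooled"
    for (idx in indices) {
      entry <- lookup_stratum(table, cohort$age[i], sex_for_lookup, idx)
      if (is.null(entry))
        stop(sprintf("cohort_z_summary: no stratum for (age %.1f, %s)",
                     cohort$age[i], cohort$sex[i]), call. = FALSE)
      zcols[i, idx] <- z_score(cohort[[idx]][i], entry$mean, entry$sd)
    }
  }

  bin <- findInterval(cohort$age, c(scheme$age_lo, scheme$age_hi[nrow(scheme)]))
  rows <- list()
  for (b in seq_len(nrow(scheme))) {
    sel <- bin == b
    if (!any(sel)) next
    for (idx in indices) {
      z <- zcols[sel, idx]
      z <- z[is.finite(z)]
      if (length(z) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        age_lo = scheme$age_lo[b], age_hi = scheme$age_hi[b],
        index = idx,
        mean_z = mean(z), sd_z = stats::sd(z),
        mean_abs_z = mean(abs(z)), sd_abs_z = stats::sd(abs(z)),
        n = sum(sel),
        n_male = sum(cohort$sex[sel] == "male"),
        n_female = sum(cohort$sex[sel] == "female"))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "subject_z") <- cbind(
    cohort[c("subject_id", "age", "sex", "group")],
    as.data.frame(zcols))
  class(out) <- c("cohort_z_summary", "data.frame")
  out
}
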