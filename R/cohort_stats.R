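#' Severity bands for the BDI-II and BAI
#'
#' Classifies a total score on the Beck Depression Inventory-II or Beck
#' Anxiety Inventory (both 21-item scales, total range 0-63) into the
#' published severity bands: BDI-II <= 13 normal, 14-19 mild, 20-28
#' moderate, >= 29 severe; BAI <= 7 normal, 8-15 mild, 16-25 moderate,
#' >= 26 severe.
#'
#' @param scale `"BDI-II"` or `"BAI"`.
#' @param score integer total score in \[0, 63\].
#' @return one of `"normal"`, `"mild"`, `"moderate"`, `"severe"`.
#' @export
classify_severity <- function(scale = c("BDI-II", "BAI"), score) {
  scale <- match.arg(scale)
  if (!is.finite(score) || score < 0 || score > 63)
    stop("classify_severity: score must lie in [0, 63]", call. = FALSE)
  cuts <- if (scale == "BDI-II") c(13, 19, 28) else c(7, 15, 25)
  c("normal", "mild", "moderate", "severe")[findInterval(score, cuts + 1L) + 1L]
}

#' Screen a participant for the normative or clinical group
#'
#' Applies the enrolment rules in order and reports the first failing one.
#' Healthy controls (HC) require age in \[20, 70), BDI-II total < 14,
#' BAI total < 8 and no severe physical or psychiatric illness. The
#' clinical group (MDD) requires age in \[20, 70), a clinician MDD
#' diagnosis, BDI-II > 14 and BAI > 8. Scores of exactly 14 (BDI-II) or
#' 8 (BAI) satisfy neither rule set and are surfaced as
#' `excluded(boundary)`.
#'
#' @param record a list or one-row data frame with fields `age`,
#'   `bdi_total`, `bai_total`, and logical flags `severe_illness`,
#'   `mdd_diagnosis` (and optionally `daytime_sleepiness`).
#' @param target_group `"HC"` or `"MDD"`.
#' @return list with `eligible` (logical) and `reason` (`""` when
#'   eligible; otherwise the first failing rule: `missing_data`, `age`,
#'   `BDI`, `BAI`, `boundary`, `illness`, `diagnosis`, `sleepiness`).
#' @export
screen_participant <- function(record, target_group = c("HC", "MDD")) {
  target_group <- match.arg(target_group)
  record <- as.list(record)
  get <- function(field, default = NULL) {
    v <- record[[field]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
  }
  excl <- function(reason) list(eligible = FALSE, reason = reason)

  age <- get("age"); bdi <- get("bdi_total"); bai <- get("bai_total")
  if (is.null(age) || is.null(bdi) || is.null(bai))
    return(excl("missing_data"))
  if (age < 20 || age >= 70) return(excl("age"))

  if (target_group == "HC") {
    if (bdi == 14 || bai == 8) return(excl("boundary"))
    if (bdi >= 14) return(excl("BDI"))
    if (bai >= 8) return(excl("BAI"))
    if (isTRUE(get("severe_illness", FALSE))) return(excl("illness"))
  } else {
    if (!isTRUE(get("mdd_diagnosis", FALSE))) return(excl("diagnosis"))
    if (bdi == 14 || bai == 8) return(excl("boundary"))
    if (bdi <= 14) return(excl("BDI"))
    if (bai <= 8) return(excl("BAI"))
    if (isTRUE(get("severe_illness", FALSE))) return(excl("illness"))
    if (isTRUE(get("daytime_sleepiness", FALSE))) return(excl("sleepiness"))
  }
  list(eligible = TRUE, reason = "")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson's chi-square without continuity correction (df = 1). The
#' correction is deliberately off: sex-distribution comparisons in the
#' normative-database literature report the uncorrected statistic.
#'
#' @param counts 2x2 matrix of counts.
#' @return list of class `htest_result` with `statistic`, `df`, `p_value`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi_square_2x2: zero marginal", call. = FALSE)
  ht <- stats::chisq.test(counts, correct = FALSE)
  if (any(ht$expected <= 0))
    stop("chi_square_2x2: non-positive expected count", call. = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 effect_size = NA_real_),
            class = "htest_result")
}

#' Pooled-variance two-sample t test
#'
#' Student's t with pooled variance, df = n1 + n2 - 2, two-sided p.
#' The first sample is conventionally the healthy-control group, fixing
#' the sign of the statistic.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list of class `htest_result` with `statistic`, `df`, `p_value`.
#' @export
student_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("student_t: each sample needs n >= 2", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("student_t: zero pooled variance", call. = FALSE)
  ht <- stats::t.test(x, y, var.equal = TRUE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 effect_size = NA_real_),
            class = "htest_result")
}

#' ANCOVA for a group effect with a retained covariate
#'
#' Least-squares fit of `y ~ group + covariate`; the group effect is
#' tested by the extra sum of squares of `group` given the covariate
#' (type-II), and its size reported as partial eta-squared
#' `SS_group / (SS_group + SS_error)`. With a covariate orthogonal to the
#' group factor this reduces exactly to one-way ANOVA.
#'
#' @param y numeric outcome.
#' @param group factor (or coercible) with >= 2 levels.
#' @param covariate numeric or factor covariate, non-constant.
#' @return list of class `htest_result` with `statistic` (F), `df`
#'   (numerator, denominator), `p_value`, `effect_size` (partial eta^2).
#' @export
ancova_group <- function(y, group, covariate) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("ancova_group: need >= 2 groups", call. = FALSE)
  if (length(unique(covariate)) < 2L)
    stop("ancova_group: covariate is constant", call. = FALSE)
  d <- data.frame(y = y, group = droplevels(group), covariate = covariate)
  full <- stats::lm(y ~ group + covariate, data = d)
  if (any(is.na(stats::coef(full))))
    stop("ancova_group: rank-deficient design", call. = FALSE)
  reduced <- stats::lm(y ~ covariate, data = d)
  ss_group <- sum(stats::resid(reduced)^2) - sum(stats::resid(full)^2)
  ss_error <- sum(stats::resid(full)^2)
  df1 <- nlevels(d$group) - 1L
  df2 <- full$df.residual
  f <- (ss_group / df1) / (ss_error / df2)
  structure(list(statistic = f, df = c(df1, df2),
                 p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                 effect_size = ss_group / (ss_group + ss_error)),
            class = "htest_result")
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric samples of equal length >= 3, both non-constant.
#' @return list with `r` and two-sided `p` from
#'   `t = r * sqrt((n - 2) / (1 - r^2))`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("pearson: need equal-length samples with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson: constant input", call. = FALSE)
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' @export
print.htest_result <- function(x, ...) {
  df <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("statistic = %.4f, df = %s, p = %.4g", x$statistic, df,
              x$p_value))
  if (is.finite(x$effect_size))
    cat(sprintf(", partial eta^2 = %.4f", x$effect_size))
  cat("\n")
  invisible(x)
}
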