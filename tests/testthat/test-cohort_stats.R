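test_that("severity bands match the published BDI-II and BAI cutoffs", {
  cases <- list(
    list("BDI-II", 0, "normal"), list("BDI-II", 13, "normal"),
    list("BDI-II", 14, "mild"), list("BDI-II", 19, "mild"),
    list("BDI-II", 20, "moderate"), list("BDI-II", 28, "moderate"),
    list("BDI-II", 29, "severe"), list("BDI-II", 63, "severe"),
    list("BAI", 7, "normal"), list("BAI", 8, "mild"),
    list("BAI", 15, "mild"), list("BAI", 16, "moderate"),
    list("BAI", 25, "moderate"), list("BAI", 26, "severe"))
  for (cs in cases)
    expect_equal(classify_severity(cs[[1]], cs[[2]]), cs[[3]],
                 label = sprintf("%s score %d", cs[[1]], cs[[2]]))
  expect_error(classify_severity("BAI", 64), "\\[0, 63\\]")
  expect_error(classify_severity("BDI-II", -1), "\\[0, 63\\]")
})

test_that("participant screening applies rules in order with first failure as reason", {
  hc_ok <- list(age = 30, bdi_total = 5, bai_total = 3,
                severe_illness = FALSE)
  expect_true(screen_participant(hc_ok, "HC")$eligible)

  young <- hc_ok; young$age <- 19
  expect_equal(screen_participant(young, "HC")$reason, "age")
  high_bdi <- hc_ok; high_bdi$bdi_total <- 20
  expect_equal(screen_participant(high_bdi, "HC")$reason, "BDI")
  ill <- hc_ok; ill$severe_illness <- TRUE
  expect_equal(screen_participant(ill, "HC")$reason, "illness")
  incomplete <- hc_ok; incomplete$bai_total <- NULL
  expect_equal(screen_participant(incomplete, "HC")$reason, "missing_data")

  mdd_ok <- list(age = 45, bdi_total = 30, bai_total = 20,
                 mdd_diagnosis = TRUE)
  expect_true(screen_participant(mdd_ok, "MDD")$eligible)
  no_dx <- mdd_ok; no_dx$mdd_diagnosis <- FALSE
  expect_equal(screen_participant(no_dx, "MDD")$reason, "diagnosis")

  # scores of exactly 14 / 8 satisfy neither rule set
  b1 <- hc_ok; b1$bdi_total <- 14
  expect_equal(screen_participant(b1, "HC")$reason, "boundary")
  b2 <- mdd_ok; b2$bai_total <- 8
  expect_equal(screen_participant(b2, "MDD")$reason, "boundary")
})

test_that("chi-square matches the direct formula and published sex table", {
  sex_table <- matrix(c(137, 174, 66, 206), nrow = 2, byrow = TRUE)
  res <- chi_square_2x2(sex_table)
  expect_equal(res$statistic, 25.030, tolerance = 1e-4)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.001)

  expect_equal(chi_square_2x2(matrix(50, 2, 2))$statistic, 0)

  brute <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  set.seed(41)
  for (rep in 1:25) {
    m <- matrix(sample(5:300, 4), 2, 2)
    res <- chi_square_2x2(m)
    expect_equal(res$statistic, brute(m), tolerance = 1e-9)
    # invariance to transposition and row swap
    expect_equal(chi_square_2x2(t(m))$statistic, res$statistic,
                 tolerance = 1e-12)
    expect_equal(chi_square_2x2(m[2:1, ])$statistic, res$statistic,
                 tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "marginal")
})

test_that("pooled t-test has additive df and matches the textbook formula", {
  set.seed(42)
  x <- rnorm(311); y <- rnorm(272)
  res <- student_t(x, y)
  expect_equal(res$df, 581)

  pooled_oracle <- function(x, y) {
    sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  }
  for (rep in 1:25) {
    a <- rnorm(sample(5:60, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1))
    expect_equal(student_t(a, b)$statistic, pooled_oracle(a, b),
                 tolerance = 1e-9)
  }
  z <- rnorm(20)
  res <- student_t(z, z)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(student_t(rep(1, 5), rep(1, 5)), "variance")
})

test_that("ANCOVA reduces to one-way ANOVA under an orthogonal covariate", {
  set.seed(43)
  g <- rep(c("HC", "MDD"), each = 40)
  covariate <- rep(c(-1, 1), 40)          # balanced: orthogonal to group
  y <- rnorm(80) + (g == "MDD") * 0.8
  # remove any chance covariate-y correlation so the covariate carries
  # exactly zero effect
  y <- y - sum(y * covariate) / sum(covariate^2) * covariate
  res <- ancova_group(y, g, covariate)
  av <- summary(stats::aov(y ~ factor(g)))[[1]]
  eta_anova <- av$`Sum Sq`[1] / sum(av$`Sum Sq`)
  expect_equal(res$effect_size, eta_anova, tolerance = 1e-9)
  # F differs from one-way only through the error df spent on the covariate
  expect_equal(res$statistic, av$`F value`[1] * res$df[2] / av$Df[2],
               tolerance = 1e-9)

  # identical groups: F ~ 0
  y0 <- rep(rnorm(40), 2)
  res0 <- ancova_group(y0, g, rnorm(80))
  expect_lt(res0$effect_size, 0.05)

  expect_error(ancova_group(y, rep("HC", 80), covariate), "2 groups")
  expect_error(ancova_group(y, g, rep(1, 80)), "constant")
})

test_that("ANCOVA agrees with the type-II analysis of an established fitter", {
  skip_if_not_installed("car")
  set.seed(44)
  n <- 120
  g <- factor(sample(c("HC", "MDD"), n, replace = TRUE))
  sex <- factor(sample(c("male", "female"), n, replace = TRUE))
  y <- rnorm(n) + (g == "MDD") * -0.5 + (sex == "female") * 0.3
  res <- ancova_group(y, g, sex)
  ca <- car::Anova(stats::lm(y ~ g + sex), type = 2)
  expect_equal(res$statistic, ca[rownames(ca) == "g", "F value"],
               tolerance = 1e-9)
  expect_equal(res$p_value, ca[rownames(ca) == "g", "Pr(>F)"],
               tolerance = 1e-9)
  ss <- ca[["Sum Sq"]]
  expect_equal(res$effect_size,
               ss[rownames(ca) == "g"] / (ss[rownames(ca) == "g"] +
                                            ss[rownames(ca) == "Residuals"]),
               tolerance = 1e-9)
})

test_that("a 1 SD group shift yields partial eta-squared near d^2/(d^2+4)", {
  set.seed(45)
  eta <- replicate(5, {
    g <- rep(c("HC", "MDD"), each = 200)
    y <- rnorm(400) + (g == "MDD") * 1
    ancova_group(y, g, rnorm(400))$effect_size
  })
  expect_true(all(eta > 0.15 & eta < 0.25))  # analytic 1/(1+4) = 0.2
})

test_that("pearson matches hand computation and is affine-invariant", {
  expect_equal(pearson(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6,
               tolerance = 1e-12)
  set.seed(46)
  x <- rnorm(30); y <- rnorm(30)
  r0 <- pearson(x, y)$r
  expect_equal(pearson(3 * x + 2, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson(x, -y)$r, -r0, tolerance = 1e-12)
  # p from the t transform of r
  n <- 30; r <- r0
  p_oracle <- 2 * stats::pt(abs(r * sqrt((n - 2) / (1 - r^2))), n - 2,
                            lower.tail = FALSE)
  expect_equal(pearson(x, y)$p, p_oracle, tolerance = 1e-9)
  expect_error(pearson(rep(1, 10), rnorm(10)), "constant")
})
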