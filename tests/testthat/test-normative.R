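test_that("norm construction uses sample mean/SD with n - 1 and drops degenerate cells", {
  cohort <- as_cohort_table(data.frame(
    subject_id = c("a", "b"), age = c(38, 42), sex = "female",
    group = "HC", bdi_total = 3, bdi_cognitive = 2, bdi_somatic = 1,
    bai_total = 2, bai_cognitive = 1, bai_somatic = 1,
    sdnn_ms = c(38, 42)))
  # ages 38 and 42 fall in different decades -> both strata degenerate
  expect_warning(expect_error(build_norm_table(cohort), "no usable"),
                 "omitted")

  cohort$age <- c(41, 43)
  nt <- build_norm_table(cohort, by_sex = "pooled")
  expect_equal(nt$mean, 40)
  expect_equal(nt$sd, 2.8284, tolerance = 1e-4)
  expect_equal(nt$n, 2)

  # zero-variance stratum is omitted with a warning
  cohort$sdnn_ms <- c(40, 40)
  expect_warning(expect_error(build_norm_table(cohort, by_sex = "pooled"),
                              "no usable"), "sd = 0")
})

test_that("norm construction recovers generator stratum means", {
  cfg <- synthetic_cohort_config(n_per_stratum = 60, seed = 42)
  hc <- gen_cohort(cfg, "HC")
  nt <- as.data.frame(build_norm_table(hc, by_sex = "pooled"))
  p <- cfg$index_params
  ok <- 0; total <- 0
  for (i in seq_len(nrow(nt))) {
    idx <- nt$index_name[i]
    mid_age <- (nt$stratum_age_lo[i] + nt$stratum_age_hi[i]) / 2
    truth <- p[idx, "intercept"] +
      p[idx, "slope_per_decade"] * (mid_age - 20) / 10 +
      p[idx, "female_offset"] / 2   # balanced sexes
    se <- p[idx, "resid_sd"] / sqrt(nt$n[i])
    # age spread within the bin inflates the tolerance slightly
    total <- total + 1
    ok <- ok + (abs(nt$mean[i] - truth) < 3 * se + 0.3 * abs(
      p[idx, "slope_per_decade"]))
  }
  expect_gte(ok / total, 0.95)
})

test_that("the embedded reference table returns the published cells", {
  ref <- taiwan_reference()
  cell <- function(sex, idx) {
    d <- as.data.frame(ref)
    d[d$sex == sex & d$index_name == idx, ]
  }
  expect_equal(cell("pooled", "sdnn_ms")$mean, 41.95)
  expect_equal(cell("pooled", "sdnn_ms")$sd, 16.26)
  expect_equal(cell("pooled", "sdnn_ms")$n, 311)
  expect_equal(cell("pooled", "rmssd_ms")$mean, 31.41)
  expect_equal(cell("pooled", "ln_tp")$sd, 0.88)
  expect_equal(cell("female", "rmssd_ms")$mean, 33.96)
  expect_equal(cell("female", "rmssd_ms")$sd, 17.23)
  expect_equal(cell("male", "ln_lf_hf")$mean, 0.35)
  expect_equal(cell("male", "ln_lf_hf")$sd, 1.05)
  expect_equal(unique(cell("male", "sdnn_ms")$n), 137)
  expect_equal(unique(cell("female", "sdnn_ms")$n), 174)
  # only all-ages strata are published
  d <- as.data.frame(ref)
  expect_true(all(d$stratum_age_lo == 20 & d$stratum_age_hi == 70))
})

test_that("z_score is exact standardization", {
  expect_equal(z_score(41.95, 41.95, 16.26), 0)
  expect_equal(z_score(41.95 + 16.26, 41.95, 16.26), 1)
  expect_equal(z_score(41.95 - 16.26, 41.95, 16.26), -1)
  expect_equal(z_score(32.99, 41.95, 16.26), -0.5510, tolerance = 1e-4)
  expect_error(z_score(1, 0, 0), "sigma")
  expect_true(is.na(z_score(NA_real_, 0, 1)))
})

test_that("z-scores are affine-equivariant", {
  set.seed(31)
  for (rep in 1:20) {
    x <- rnorm(1); mu <- rnorm(1); sigma <- runif(1, 0.5, 3)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(z_score(a * x + b, a * mu + b, a * sigma),
                 z_score(x, mu, sigma), tolerance = 1e-9)
  }
})

test_that("z_report uses the fallback chain and strict deviation threshold", {
  nt <- toy_norm_table()
  # (age-bin, sex) preferred
  rep1 <- z_report(sdnn_only(45), 35, "female", nt)
  expect_equal(rep1$z, 0)
  expect_equal(rep1$stratum_sex, "female")
  # no male bin entry -> (age-bin, pooled)
  rep2 <- z_report(sdnn_only(44), 35, "male", nt)
  expect_equal(rep2$z, 0)
  expect_equal(rep2$stratum_sex, "pooled")
  expect_equal(rep2$stratum_age_lo, 30)
  # outside the bin -> all-ages pooled
  rep3 <- z_report(sdnn_only(40), 55, "male", nt)
  expect_equal(rep3$z, 0)
  expect_equal(rep3$stratum_age_hi, 70)
  # missing stratum is an error naming the gap
  only_bin <- norm_table(data.frame(stratum_age_lo = 30, stratum_age_hi = 40,
                                    sex = "pooled", index_name = "sdnn_ms",
                                    mean = 44, sd = 14, n = 40))
  expect_error(z_report(sdnn_only(40), 55, "male", only_bin), "55")

  # boundary: |z| = 1.96 exactly is NOT deviant (strict inequality)
  at_bound <- z_report(sdnn_only(40 + 1.96 * 16), 55, "male", nt)
  expect_equal(at_bound$z, 1.96)
  expect_false(at_bound$deviant)
  beyond <- z_report(sdnn_only(40 + 1.961 * 16), 55, "male", nt)
  expect_true(beyond$deviant)
})

test_that("a subject generated 2.5 SD below the norm is flagged deviant", {
  cfg <- synthetic_cohort_config(n_per_stratum = 100, seed = 13)
  hc <- gen_cohort(cfg, "HC")
  nt <- build_norm_table(hc, by_sex = "pooled")
  entry <- as.data.frame(nt)
  stopifnot(!anyDuplicated(paste(entry$stratum_age_lo, entry$index_name)))
  e <- entry[entry$stratum_age_lo == 40 & entry$index_name == "ln_tp", ]
  subject <- list(ln_tp = e$mean - 2.5 * e$sd)
  rep <- z_report(subject, 45, "female", nt)
  expect_equal(rep$z, -2.5, tolerance = 1e-9)
  expect_true(rep$deviant)
})

test_that("cohort z-summary self-normalizes and reflects generator offsets", {
  cfg <- synthetic_cohort_config(n_per_stratum = 60, seed = 8)
  hc <- gen_cohort(cfg, "HC")
  nt <- build_norm_table(hc, by_sex = "pooled")
  zsum <- cohort_z_summary(hc, nt)
  # norming cohort against its own norms: stratum means are ~0
  for (i in seq_len(nrow(zsum)))
    expect_lt(abs(zsum$mean_z[i]), 3 / sqrt(zsum$n[i]))
  # Jensen: mean |z| >= |mean z|
  expect_true(all(zsum$mean_abs_z >= abs(zsum$mean_z) - 1e-12))

  # MDD cohort from the same config shifted by -0.55 residual SD
  mdd <- gen_cohort(synthetic_cohort_config(n_per_stratum = 60, seed = 88),
                    "MDD")
  zmdd <- cohort_z_summary(mdd, nt)
  expect_lt(mean(zmdd$mean_z[zmdd$index == "sdnn_ms"]), -0.2)
  expect_gt(mean(zmdd$mean_z[zmdd$index == "sdnn_ms"]), -1.0)
})

test_that("constant cohort at mu + sigma gives mean z = 1 with zero spread", {
  nt <- toy_norm_table()
  n <- 12
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("s%02d", 1:n),
    age = runif(n, 30, 40), sex = rep(c("male", "female"), n / 2),
    group = "HC", bdi_total = 3, bdi_cognitive = 2, bdi_somatic = 1,
    bai_total = 2, bai_cognitive = 1, bai_somatic = 1,
    sdnn_ms = 44 + 14))  # bin entry mu = 44, sigma = 14
  zsum <- cohort_z_summary(cohort, nt)
  expect_equal(zsum$mean_z, 1, tolerance = 1e-12)
  expect_equal(zsum$sd_z, 0, tolerance = 1e-12)
  expect_equal(zsum$n_male, 6)
  expect_equal(zsum$n_female, 6)
})
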