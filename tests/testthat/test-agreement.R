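# Agreement statistics: CCC, Pearson, error metrics, Bland-Altman,
# paired t, Fisher Z, stratified reports.

test_that("ccc is 1 on identity, -1 on reflection, and matches its formula", {
  x <- c(2, 4, 6, 8, 11)
  expect_equal(ccc(x, x)$est, 1)
  z <- c(-2, -1, 0, 1, 2)                      # zero mean
  expect_equal(ccc(z, -z)$est, -1)
  # independent evaluation of the population-moment formula
  x4 <- c(1, 2, 3, 4); y4 <- c(1.1, 2.0, 3.2, 3.9)
  mx <- mean(x4); my <- mean(y4)
  num <- 2 * mean((x4 - mx) * (y4 - my))
  den <- mean((x4 - mx)^2) + mean((y4 - my)^2) + (mx - my)^2
  expect_equal(ccc(x4, y4)$est, num / den)
  expect_error(ccc(c(1, 1, 1), c(1, 1, 1)), "undefined")
})

test_that("ccc CI contains the estimate and narrows with n", {
  set.seed(5)
  x <- rnorm(30, 20, 5); y <- x + rnorm(30, 0, 1)
  small <- ccc(x, y)
  xx <- rnorm(600, 20, 5); yy <- xx + rnorm(600, 0, 1)
  big <- ccc(xx, yy)
  expect_true(small$lwr <= small$est && small$est <= small$upr)
  expect_lt(big$upr - big$lwr, small$upr - small$lwr)
})

test_that("pearson r ignores affine bias and matches cor.test machinery", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0)
  expect_equal(pearson_ci(x, 2 * x + 3)$est, 1)
  set.seed(8)
  y <- x + rnorm(6)
  ours <- pearson_ci(x, y)
  ref <- cor.test(x, y)                         # independent implementation
  expect_equal(ours$est, unname(ref$estimate))
  expect_equal(c(ours$lwr, ours$upr), as.numeric(ref$conf.int),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pearson_ci(rep(1, 5), 1:5), "constant")
})

test_that("independent pairs give near-zero correlation at large n", {
  set.seed(9)
  x <- rnorm(1e4); y <- rnorm(1e4)
  expect_lt(abs(pearson_ci(x, y)$est), 0.05)
})

test_that("error metrics reproduce hand-computed MAE and RMSE", {
  x <- c(5, 5, 8); y <- c(5, 5, 5)             # diffs 0, 0, 3
  em <- error_metrics(x, y, n_boot = 200, seed = 1)
  expect_equal(em$mae$est, 1)
  expect_equal(em$rmse$est, sqrt(3))
  z <- c(1, -1, 1, -1)
  em2 <- error_metrics(z, rep(0, 4), n_boot = 200, seed = 1)
  expect_equal(em2$mae$est, 1)
  expect_equal(em2$rmse$est, 1)
  expect_equal(error_metrics(x, x, n_boot = 200, seed = 1)$rmse$est, 0)
})

test_that("bootstrap intervals are reproducible bit-for-bit given the seed", {
  set.seed(11)
  x <- rnorm(50); y <- x + rnorm(50, 0, 0.5)
  a <- error_metrics(x, y, n_boot = 500, seed = 99)
  b <- error_metrics(x, y, n_boot = 500, seed = 99)
  expect_identical(a, b)
  c2 <- error_metrics(x, y, n_boot = 500, seed = 100)
  expect_false(identical(a$mae$lwr, c2$mae$lwr))
  expect_warning(error_metrics(x, y, n_boot = 50, seed = 1), "small")
})

test_that("MAE never exceeds RMSE", {
  set.seed(12)
  for (rep in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    em <- error_metrics(x, y, n_boot = 100, seed = rep)
    expect_lte(em$mae$est, em$rmse$est + 1e-12)
  }
})

test_that("|CCC| <= |r| on randomized inputs (Lin's inequality)", {
  set.seed(13)
  for (rep in 1:30) {
    x <- rnorm(25, 10, 3)
    y <- runif(1, -2, 2) * x + rnorm(25, runif(1, -5, 5), 2)
    cc <- ccc(x, y)$est
    r <- cor(x, y)
    expect_lte(abs(cc), abs(r) + 1e-12)
  }
})

test_that("CCC equals r exactly when means and variances coincide", {
  set.seed(14)
  x <- rnorm(200)
  y <- sample(x)           # identical mean and variance, shuffled pairing
  expect_equal(ccc(x, y)$est, cor(x, y), tolerance = 1e-12)
})

test_that("bland_altman on identical inputs is fully degenerate", {
  x <- c(3, 7, 9, 12)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias_mm, 0)
  expect_equal(ba$loa_low_mm, 0)
  expect_equal(ba$loa_high_mm, 0)
  expect_equal(ba$prop_bias_slope, 0)
})

test_that("Bland-Altman coverage is ~95% under a normal null", {
  set.seed(15)
  x <- rnorm(1e4, 25, 10)
  y <- x + rnorm(1e4, 0, 1)
  ba <- bland_altman(x, y)
  expect_lt(abs(ba$pct_within_loa - 95), 1)
  expect_lt(abs((ba$loa_high_mm - ba$loa_low_mm) / 2 - 1.96), 0.06)
})

test_that("planted proportional bias is recovered", {
  set.seed(16)
  m <- runif(400, 10, 40)
  x <- m + 0.05 * m + rnorm(400, 0, 0.2)
  y <- m - 0.05 * m + rnorm(400, 0, 0.2)       # x - y = 0.1 * mean approx
  ba <- bland_altman(x, y)
  expect_equal(ba$prop_bias_slope, 0.1, tolerance = 0.02)
  expect_lt(ba$prop_bias_p, 0.01)
})

test_that("paired t statistic matches hand computation", {
  expect_equal(paired_t(c(0, 2), c(1, 1))$t, 0)
  expect_equal(paired_t(c(0, 2), c(1, 1))$p_value, 1)
  pt3 <- paired_t(c(2, 4, 6), c(1, 2, 3))      # diffs 1, 2, 3
  expect_equal(pt3$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "zero variance")
  set.seed(17)
  x <- rnorm(100); y <- x - 1 + rnorm(100, 0, 0.3)
  expect_lt(paired_t(x, y)$p_value, 1e-3)
})

test_that("fisher Z matches hand computation and is antisymmetric", {
  fz <- fisher_z(0.9, 103, 0.8, 103)
  expect_equal(fz$z, (atanh(0.9) - atanh(0.8)) / sqrt(2 / 100),
               tolerance = 1e-12)
  expect_equal(fz$z, 2.642, tolerance = 1e-3)
  rev <- fisher_z(0.8, 103, 0.9, 103)
  expect_equal(rev$z, -fz$z)
  expect_equal(rev$p_value, fz$p_value)
  expect_equal(fisher_z(0.5, 50, 0.5, 80)$z, 0)
  expect_equal(fisher_z(0.5, 50, 0.5, 80)$p_value, 1)
  expect_error(fisher_z(1, 50, 0.5, 50), "undefined")
})

test_that("stratified agreement recovers a sex-specific planted bias", {
  co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 25, seed = 31))
  co <- gen_paired_measurements(co, bias_mm = 0, noise_sd_mm = 0.3, seed = 32)
  male <- co$sex == "male"
  co$size_mm[male] <- co$size_mm[male] + 0.6    # AI overestimates in males
  rep <- stratified_agreement(co, by = "sex", n_boot = 200, seed = 1)
  expect_gt(abs(rep$bias_mm[rep$stratum == "male"]), 0.4)
  expect_lt(abs(rep$bias_mm[rep$stratum == "female"]), 0.1)
})

test_that("a single stratum reproduces the unstratified analysis", {
  co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 10, seed = 41))
  co <- gen_paired_measurements(co, 0, 0.5, seed = 42)
  rep <- stratified_agreement(co, by = character(0), n_boot = 200, seed = 3)
  direct <- agreement_report(co$size_mm, co$reference_mm,
                             n_boot = 200, seed = 3)
  expect_equal(rep$ccc, direct$ccc)
  expect_equal(rep$bias_mm, direct$bias_mm)
  expect_equal(nrow(rep), 1L)
})

test_that("the sex-by-age design yields 24 subgroup reports", {
  co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 5, seed = 51))
  co <- gen_paired_measurements(co, 0, 0.5, seed = 52)
  rep <- stratified_agreement(co, by = c("sex", "age"), n_boot = 100, seed = 1)
  expect_equal(nrow(rep), 1 + 24)              # overall + 12 bins x 2 sexes
  expect_false(any(rep$insufficient))
})

test_that("small strata are flagged insufficient, not dropped", {
  co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 3, seed = 61))
  co <- gen_paired_measurements(co, 0, 0.5, seed = 62)
  co <- co[co$sex == "female" | cumsum(co$sex == "male") <= 2, ]
  rep <- stratified_agreement(co, by = "sex", n_boot = 100, seed = 1)
  expect_true("male" %in% rep$stratum)
  expect_true(rep$insufficient[rep$stratum == "male"])
  expect_error(stratified_agreement(co, by = "height"), "unknown stratum")
})
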