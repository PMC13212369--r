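# Synthetic-data generator: masks with analytic truth, anchored cohorts,
# simulated paired readings.

test_that("analytic mask truth matches closed-form special cases", {
  g <- gen_fhoc_mask(shape_params(50, 40), image_shape = c(201, 201),
                     spacing_mm = 0.2)
  expect_equal(g$truth$diameter_mm, 20)                 # 2 a s
  g90 <- gen_fhoc_mask(shape_params(50, 40, rotation_deg = 90),
                       image_shape = c(201, 201), spacing_mm = 0.2)
  expect_equal(g90$truth$diameter_mm, 16)               # axes swap
  for (rot in c(0, 33, 90, 145)) {
    gc <- gen_fhoc_mask(shape_params(30, 30, rotation_deg = rot),
                        image_shape = c(101, 101), spacing_mm = 0.1)
    expect_equal(gc$truth$diameter_mm, 6)               # circle invariant
  }
})

test_that("masks have exactly one foreground component", {
  for (seed in 71:80) {
    g <- gen_fhoc_mask(random_shape(seed), image_shape = c(101, 101),
                       spacing_mm = 0.2, seed = seed)
    expect_equal(fhocgrowth:::label_components(g$mask$pixels)$n, 1L)
  }
})

test_that("shapes exceeding the image raise an axis-specific error", {
  expect_error(gen_fhoc_mask(shape_params(60, 20), image_shape = c(101, 101)),
               "column")
  expect_error(gen_fhoc_mask(shape_params(20, 60), image_shape = c(101, 101)),
               "row")
})

test_that("shape parameter invariants are enforced", {
  expect_error(shape_params(-1, 5), "positive")
  expect_error(shape_params(5, 5, crescent_fraction = 0.7), "crescent")
  expect_error(shape_params(5, 5, boundary_noise_sd = -1), ">= 0")
})

test_that("a deep crescent cut moves the analytic landmarks onto the cut", {
  # cut high enough that the transverse extreme of the tilted ellipse is
  # removed: landmark moves to the cut line, shortening the true chord
  p <- shape_params(40, 30, rotation_deg = 40, crescent_fraction = 0.45)
  g <- gen_fhoc_mask(p, image_shape = c(121, 121), spacing_mm = 0.2)
  full <- gen_fhoc_mask(shape_params(40, 30, rotation_deg = 40),
                        image_shape = c(121, 121), spacing_mm = 0.2)
  expect_lt(g$truth$diameter_mm, full$truth$diameter_mm)
  tr <- fhocgrowth:::.shape_truth(p, 60, 60)
  expect_equal(unname(tr$p_right["row"]), tr$rowcut)
  # the measured chord of the truncated mask equals the exhaustive
  # boundary-search chord (pixel-level oracle)
  m <- measure_mask(g$mask)
  orc <- oracle_landmarks(g$mask$pixels)
  expect_equal(unname(m$landmarks$medial), unname(orc$left))
  expect_equal(unname(m$landmarks$lateral), unname(orc$right))
})

test_that("shallow-cut crescents keep the full-ellipse chord", {
  p <- shape_params(40, 30, rotation_deg = 30, crescent_fraction = 0.3)
  g <- gen_fhoc_mask(p, image_shape = c(121, 121), spacing_mm = 0.2)
  full <- gen_fhoc_mask(shape_params(40, 30, rotation_deg = 30),
                        image_shape = c(121, 121), spacing_mm = 0.2)
  # cut lies below the transverse extremes: analytic chord unchanged,
  # but pixels are removed
  expect_equal(g$truth$diameter_mm, full$truth$diameter_mm)
  expect_lt(sum(g$mask$pixels), sum(full$mask$pixels))
})

test_that("anchor table validation rejects crossing or dipping quantiles", {
  anch <- default_anchor_table()
  expect_s3_class(anch, "data.frame")
  bad <- anch
  bad$q5_mm[3] <- bad$q50_mm[3] + 1
  expect_error(validate_anchor_table(bad), "cross")
  dip <- anch
  dip$q50_mm[anch$sex == "female" & anch$age_years == 5] <-
    dip$q50_mm[anch$sex == "female" & anch$age_years == 4] - 1
  expect_error(validate_anchor_table(dip), "non-decreasing")
})

test_that("cohorts are deterministic, balanced, and structurally valid", {
  cfg <- generator_config(n_per_sex_per_agegroup = 8, seed = 123)
  co1 <- gen_cohort(cfg)
  co2 <- gen_cohort(cfg)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 8 * 12 * 2 * 2)      # n x bins x sexes x sides
  expect_true(all(co1$size_mm > 0))
  expect_true(all(co1$age_years >= 0.5 & co1$age_years <= 11))
  expect_false(any(duplicated(co1[, c("child_id", "side")])))
  # every child has exactly one left and one right row
  expect_true(all(table(co1$child_id) == 2))
})

test_that("perfect bilateral correlation makes left and right identical", {
  co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 6,
                                    bilateral_corr = 1, seed = 5))
  wide <- reshape(co[, c("child_id", "side", "size_mm")],
                  idvar = "child_id", timevar = "side", direction = "wide")
  expect_equal(wide$size_mm.left, wide$size_mm.right, tolerance = 1e-12)
})

test_that("the generating median matches the anchors at every anchor age", {
  anch <- default_anchor_table()
  for (s in c("female", "male")) {
    itp <- fhocgrowth:::anchor_interpolators(anch, s)
    sub <- anch[anch$sex == s, ]
    set.seed(77)
    for (i in seq_len(nrow(sub))) {
      draws <- fhocgrowth:::.size_from_z(itp, rep(sub$age_years[i], 1e5),
                                         rnorm(1e5))
      expect_lt(abs(median(draws) - sub$q50_mm[i]) / sub$q50_mm[i], 0.01)
    }
  }
})

test_that("per-age-bin cohort medians track the interpolated anchor median", {
  co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 850, seed = 7))
  anch <- default_anchor_table()
  bins <- default_age_bins()
  for (s in c("female", "male")) {
    itp <- fhocgrowth:::anchor_interpolators(anch, s)
    sub <- co[co$sex == s, ]
    for (i in seq_len(nrow(bins))) {
      sel <- sub$age_years >= bins[i, 1] & sub$age_years < bins[i, 2]
      med <- median(sub$size_mm[sel])
      ref <- median(itp$mu(sub$age_years[sel]))
      expect_lt(abs(med - ref) / ref, 0.02)
    }
  }
})

test_that("paired measurements implement the additive reader model", {
  co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 5, seed = 2))
  same <- gen_paired_measurements(co, bias_mm = 0, noise_sd_mm = 0)
  expect_equal(same$reference_mm, same$size_mm)
  shifted <- gen_paired_measurements(co, bias_mm = 0.5, noise_sd_mm = 0)
  expect_equal(mean(shifted$reference_mm - shifted$size_mm), 0.5)
  expect_error(gen_paired_measurements(co, 0, -1), ">= 0")
  a <- gen_paired_measurements(co, 0, 1, seed = 9)
  b <- gen_paired_measurements(co, 0, 1, seed = 9)
  expect_identical(a, b)
})

test_that("limits of agreement follow the generating noise closed form", {
  co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 209, seed = 3))
  co <- gen_paired_measurements(co, bias_mm = 0, noise_sd_mm = 1, seed = 4)
  ba <- bland_altman(co$size_mm, co$reference_mm)
  half <- (ba$loa_high_mm - ba$loa_low_mm) / 2
  expect_lt(abs(half - 1.96) / 1.96, 0.05)
})
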