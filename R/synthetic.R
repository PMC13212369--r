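#' Default age bins for subgroup analyses
#'
#' The twelve age subgroups used throughout: 0.5-0.75, 0.75-1, 1-2, 2-3, ...,
#' 10-11 years (intervals are `[lo, hi)`, the last closed on the right).
#'
#' @return 12 x 2 numeric matrix with columns `lo` and `hi` (years).
#' @export
default_age_bins <- function() {
  lo <- c(0.5, 0.75, 1:10)
  hi <- c(0.75, 1, 2:11)
  cbind(lo = lo, hi = hi)
}

#' Per-age percentile anchor table for the size generator
#'
#' Reference 5th/50th/95th FHOC size percentiles by sex at ages 0.5 and 1-11
#' years, shipped with the package. The generator interpolates these anchors
#' to define its age-dependent size distribution.
#'
#' @param path optional CSV with columns `sex`, `age_years`, `q5_mm`,
#'   `q50_mm`, `q95_mm`; defaults to the bundled table.
#' @return Validated data.frame of anchors.
#' @export
default_anchor_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fhoc_percentile_anchors.csv",
                        package = "fhocgrowth", mustWork = TRUE)
  validate_anchor_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname default_anchor_table
#' @param anchors candidate anchor data.frame (checked and returned).
#' @export
validate_anchor_table <- function(anchors) {
  need <- c("sex", "age_years", "q5_mm", "q50_mm", "q95_mm")
  if (!all(need %in% names(anchors)))
    stop("anchor table needs columns: ", paste(need, collapse = ", "))
  if (any(anchors$q5_mm >= anchors$q50_mm | anchors$q50_mm >= anchors$q95_mm))
    stop("anchor quantiles cross: need q5 < q50 < q95 at every age")
  for (s in unique(anchors$sex)) {
    sub <- anchors[anchors$sex == s, ]
    sub <- sub[order(sub$age_years), ]
    if (any(diff(sub$q50_mm) < 0))
      stop("anchor median must be non-decreasing in age (sex = ", s, ")")
  }
  anchors
}

# Monotone piecewise-cubic interpolators of the anchors for one sex.
# The per-age size model is a two-piece normal parameterized in the quantile
# domain: size = q50 + z * sigma_hi for z >= 0 and q50 + z * sigma_lo for
# z < 0 (z standard normal), with sigma_lo = (q50 - q5)/z95 and
# sigma_hi = (q95 - q50)/z95. This reproduces the 5th, 50th and 95th anchor
# percentiles exactly even when they are skewed; for symmetric anchors it is
# the plain Normal(q50, (q95 - q5)/(2 z95)).
anchor_interpolators <- function(anchors, sex) {
  sub <- anchors[anchors$sex == sex, ]
  if (nrow(sub) < 2) stop("no anchors for sex ", sex)
  sub <- sub[order(sub$age_years), ]
  mu <- stats::splinefun(sub$age_years, sub$q50_mm, method = "monoH.FC")
  f5 <- stats::splinefun(sub$age_years, sub$q5_mm, method = "monoH.FC")
  f95 <- stats::splinefun(sub$age_years, sub$q95_mm, method = "monoH.FC")
  z <- stats::qnorm(0.95)
  list(mu = mu,
       q5 = f5, q95 = f95,
       sigma = function(a) (f95(a) - f5(a)) / (2 * z),
       sigma_lo = function(a) (mu(a) - f5(a)) / z,
       sigma_hi = function(a) (f95(a) - mu(a)) / z,
       age_range = range(sub$age_years))
}

# map standard-normal draws through the two-piece size model at given ages
.size_from_z <- function(itp, age, z) {
  itp$mu(age) + ifelse(z >= 0, itp$sigma_hi(age), itp$sigma_lo(age)) * z
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a balanced design of
#' `n_per_sex_per_agegroup` children per sex in each of the twelve age bins
#' (default 25, i.e. 600 children and 1200 hips), ages uniform within bins,
#' and per-age size distributions that are two-piece normal with the 5th,
#' 50th and 95th percentiles of the (monotone piecewise-cubic interpolated)
#' anchor table -- i.e. normal tails of width `(q50 - q5)/z95` below and
#' `(q95 - q50)/z95` above the median. Left and right hips are drawn
#' from a bivariate normal with correlation `bilateral_corr` (default 0.98,
#' reflecting the near-identity of the two sides). A simulated manual reader
#' re-measures with additive bias `reader_bias_mm` and noise
#' `reader_noise_sd_mm` (default 0.96 mm, giving ~ +/-1.9 mm limits of
#' agreement).
#'
#' @param n_per_sex_per_agegroup children per sex per age bin.
#' @param age_bins 2-column matrix of `[lo, hi)` bins; default
#'   [default_age_bins()].
#' @param anchor_table anchors as in [default_anchor_table()].
#' @param bilateral_corr correlation of left and right sizes, in `[-1, 1]`.
#' @param reader_bias_mm,reader_noise_sd_mm simulated reader bias and noise.
#' @param seed integer seed; all generator randomness flows from it.
#' @return List of class `fhoc_generator_config`.
#' @export
generator_config <- function(n_per_sex_per_agegroup = 25,
                             age_bins = default_age_bins(),
                             anchor_table = default_anchor_table(),
                             bilateral_corr = 0.98,
                             reader_bias_mm = 0,
                             reader_noise_sd_mm = 0.96,
                             seed = 1) {
  stopifnot(n_per_sex_per_agegroup >= 1,
            bilateral_corr >= -1, bilateral_corr <= 1,
            reader_noise_sd_mm >= 0)
  anchor_table <- validate_anchor_table(anchor_table)
  age_bins <- as.matrix(age_bins)
  if (ncol(age_bins) != 2 || any(age_bins[, 2] <= age_bins[, 1]))
    stop("age_bins must be a 2-column matrix with hi > lo")
  structure(list(n_per_sex_per_agegroup = as.integer(n_per_sex_per_agegroup),
                 age_bins = age_bins,
                 anchor_table = anchor_table,
                 bilateral_corr = bilateral_corr,
                 reader_bias_mm = reader_bias_mm,
                 reader_noise_sd_mm = reader_noise_sd_mm,
                 seed = as.integer(seed)),
            class = "fhoc_generator_config")
}

#' Generate a synthetic bilateral measurement cohort
#'
#' Draws a cohort with the statistical structure the downstream analyses
#' assume (see [generator_config()]): per child, an age uniform in its bin
#' and a left/right size pair from a bivariate normal around the anchored
#' age-dependent mean. Sizes are truncated to be positive (non-positive
#' pairs are redrawn). Deterministic given the config seed.
#'
#' @param config an [generator_config()] object.
#' @return data.frame with columns `child_id`, `age_years`, `sex`, `side`,
#'   `size_mm`, `reference_mm` (NA until [gen_paired_measurements()] is
#'   applied); two rows (left and right) per child.
#' @export
gen_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "fhoc_generator_config"))
  set.seed(config$seed)
  rho <- config$bilateral_corr
  rows <- vector("list", 2 * nrow(config$age_bins))
  k <- 0
  counter <- c(female = 0L, male = 0L)
  for (sex in c("female", "male")) {
    itp <- anchor_interpolators(config$anchor_table, sex)
    for (b in seq_len(nrow(config$age_bins))) {
      n <- config$n_per_sex_per_agegroup
      lo <- config$age_bins[b, 1]; hi <- config$age_bins[b, 2]
      age <- stats::runif(n, lo, hi)
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      zr <- rho * z1 + sqrt(max(0, 1 - rho^2)) * z2
      left <- .size_from_z(itp, age, z1)
      right <- .size_from_z(itp, age, zr)
      # truncate at > 0 by redrawing the offending pairs
      for (tries in 1:100) {
        bad <- which(left <= 0 | right <= 0)
        if (!length(bad)) break
        z1b <- stats::rnorm(length(bad)); z2b <- stats::rnorm(length(bad))
        zrb <- rho * z1b + sqrt(max(0, 1 - rho^2)) * z2b
        left[bad] <- .size_from_z(itp, age[bad], z1b)
        right[bad] <- .size_from_z(itp, age[bad], zrb)
      }
      left <- pmax(left, 0.01); right <- pmax(right, 0.01)
      ids <- sprintf("%s%05d", toupper(substr(sex, 1, 1)),
                     counter[sex] + seq_len(n))
      counter[sex] <- counter[sex] + n
      k <- k + 1
      rows[[k]] <- data.frame(
        child_id = rep(ids, each = 2),
        age_years = rep(age, each = 2),
        sex = sex,
        side = rep(c("left", "right"), times = n),
        size_mm = as.vector(rbind(left, right)),
        reference_mm = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate paired reader measurements for a cohort
#'
#' Adds `reference_mm = size_mm + bias_mm + Normal(0, noise_sd_mm)` row-wise,
#' emulating an independent manual reading of the same hips. Deterministic
#' given `seed`.
#'
#' @param cohort cohort data.frame with `size_mm`.
#' @param bias_mm systematic offset of the simulated reader (mm).
#' @param noise_sd_mm standard deviation of the reader noise (mm, `>= 0`).
#' @param seed integer seed.
#' @return The cohort with `reference_mm` filled in.
#' @export
gen_paired_measurements <- function(cohort, bias_mm = 0, noise_sd_mm = 0.96,
                                    seed = 1) {
  if (!"size_mm" %in% names(cohort)) stop("cohort must have a size_mm column")
  if (noise_sd_mm < 0) stop("noise_sd_mm must be >= 0")
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  cohort$reference_mm <- cohort$size_mm + bias_mm +
    stats::rnorm(n, 0, noise_sd_mm)
  cohort
}

#' Shape parameters of a synthetic ossification-center mask
#'
#' An ellipse (optionally rotated, with smooth radial boundary noise) whose
#' inferior portion can be removed to mimic a partially ossified,
#' crescent-shaped center.
#'
#' @param semi_axis_a,semi_axis_b positive semi-axes in pixels (`a` along the
#'   ellipse's own first axis, horizontal at `rotation_deg = 0`).
#' @param rotation_deg rotation of the `a` axis in the image plane, degrees.
#' @param center `(row, col)` center in 0-based pixel coordinates; default is
#'   the image center at generation time.
#' @param boundary_noise_sd amplitude (pixels) of a smooth random radial
#'   perturbation of the boundary.
#' @param crescent_fraction fraction in `[0, 0.5]` of the vertical extent
#'   removed from below.
#' @return List of class `fhoc_shape_params`.
#' @export
shape_params <- function(semi_axis_a, semi_axis_b, rotation_deg = 0,
                         center = NULL, boundary_noise_sd = 0,
                         crescent_fraction = 0) {
  if (semi_axis_a <= 0 || semi_axis_b <= 0)
    stop("semi-axes must be positive")
  if (crescent_fraction < 0 || crescent_fraction > 0.5)
    stop("crescent_fraction must lie in [0, 0.5]")
  if (boundary_noise_sd < 0) stop("boundary_noise_sd must be >= 0")
  structure(list(semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
                 rotation_deg = rotation_deg, center = center,
                 boundary_noise_sd = boundary_noise_sd,
                 crescent_fraction = crescent_fraction),
            class = "fhoc_shape_params")
}

# analytic extreme-column landmarks and chord of the noiseless shape.
# Parametrization: boundary point (x, y) = (a cos t, b sin t) in the ellipse
# frame; image col = c0 + x cos th - y sin th, row = r0 + x sin th + y cos th.
.shape_truth <- function(params, r0, c0) {
  a <- params$semi_axis_a; b <- params$semi_axis_b
  th <- params$rotation_deg * pi / 180
  A <- sqrt((a * cos(th))^2 + (b * sin(th))^2)   # horizontal half-extent
  B <- sqrt((a * sin(th))^2 + (b * cos(th))^2)   # vertical half-extent
  drow <- (a^2 - b^2) * sin(th) * cos(th) / A
  p_max <- c(row = r0 + drow, col = c0 + A)
  p_min <- c(row = r0 - drow, col = c0 - A)
  rowcut <- r0 + (1 - 2 * params$crescent_fraction) * B
  clip <- function(p, want_max) {
    if (p["row"] <= rowcut + 1e-12) return(p)
    # extreme column moves to the crescent cut: ellipse/line intersection
    Rp <- rowcut - r0
    psi <- atan2(b * cos(th), a * sin(th))
    dt <- acos(max(-1, min(1, Rp / B)))
    ts <- c(psi - dt, psi + dt)
    cols <- c0 + a * cos(th) * cos(ts) - b * sin(th) * sin(ts)
    c(row = rowcut, col = if (want_max) max(cols) else min(cols))
  }
  p_max <- clip(p_max, TRUE)
  p_min <- clip(p_min, FALSE)
  list(p_left = p_min, p_right = p_max,
       diameter_px = sqrt(sum((p_max - p_min)^2)),
       rowcut = rowcut, half_extent = c(horizontal = A, vertical = B))
}

#' Generate a synthetic FHOC mask with analytic ground truth
#'
#' Rasterizes the shape described by [shape_params()] into a binary mask and
#' returns, alongside it, the true extreme-column landmark coordinates and
#' chord length computed analytically from the noiseless shape. The mask has
#' exactly one connected foreground component.
#'
#' @param params an [shape_params()] object.
#' @param image_shape `(rows, cols)` of the mask.
#' @param spacing_mm mm per pixel (isotropic).
#' @param seed integer seed for the boundary noise.
#' @return List with `mask` (an [fhoc_mask()]) and `truth` (list with
#'   `p_left`, `p_right` -- 0-based `(row, col)` landmark coordinates on the
#'   image-left and image-right side -- and `diameter_mm`).
#' @examples
#' g <- gen_fhoc_mask(shape_params(50, 40), image_shape = c(201, 201),
#'                    spacing_mm = 0.2)
#' g$truth$diameter_mm  # 20
#' @export
gen_fhoc_mask <- function(params, image_shape = c(128, 128), spacing_mm = 0.2,
                          seed = 1) {
  stopifnot(inherits(params, "fhoc_shape_params"))
  nr <- image_shape[1]; nc <- image_shape[2]
  ctr <- params$center
  if (is.null(ctr)) ctr <- c((nr - 1) / 2, (nc - 1) / 2)
  r0 <- ctr[1]; c0 <- ctr[2]
  truth <- .shape_truth(params, r0, c0)
  margin <- 3 * params$boundary_noise_sd
  A <- truth$half_extent["horizontal"]; B <- truth$half_extent["vertical"]
  if (c0 - A - margin < 0 || c0 + A + margin > nc - 1)
    stop("shape exceeds image bounds along the transverse (column) axis")
  if (r0 - B - margin < 0 || r0 + B + margin > nr - 1)
    stop("shape exceeds image bounds along the vertical (row) axis")

  a <- params$semi_axis_a; b <- params$semi_axis_b
  th <- params$rotation_deg * pi / 180
  # smooth radial noise field: low-order random Fourier series in the
  # boundary angle, sd approximately boundary_noise_sd pixels
  K <- 6L
  if (params$boundary_noise_sd > 0) {
    set.seed(as.integer(seed))
    cf <- stats::rnorm(K, 0, params$boundary_noise_sd / sqrt(K))
    sf <- stats::rnorm(K, 0, params$boundary_noise_sd / sqrt(K))
  } else {
    cf <- sf <- rep(0, K)
  }
  rows0 <- matrix(rep(0:(nr - 1), nc), nr, nc)
  cols0 <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  dx <- cols0 - c0; dy <- rows0 - r0
  xe <- dx * cos(th) + dy * sin(th)      # ellipse-frame coordinates
  ye <- -dx * sin(th) + dy * cos(th)
  phi <- atan2(ye, xe)                   # polar angle in the ellipse frame
  r_pix <- sqrt(xe^2 + ye^2)
  r_ell <- 1 / sqrt((cos(phi) / a)^2 + (sin(phi) / b)^2)
  noise <- matrix(0, nr, nc)
  for (k in seq_len(K))
    noise <- noise + cf[k] * cos(k * phi) + sf[k] * sin(k * phi)
  inside <- r_pix <= pmax(r_ell + noise, 1)
  inside <- inside & (rows0 <= truth$rowcut + 1e-9)
  mask <- fhoc_mask(inside, spacing_mm)
  list(mask = mask,
       truth = list(p_left = truth$p_left, p_right = truth$p_right,
                    diameter_mm = truth$diameter_px * spacing_mm,
                    params = params, spacing_mm = spacing_mm))
}
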