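#' Lin's concordance correlation coefficient with 95% CI
#'
#' Agreement of paired measurements around the line of identity:
#' `CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments. The confidence interval uses the inverse
#' hyperbolic tangent (Fisher-type) transform with Lin's (1989) asymptotic
#' variance of the transformed estimate.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @param conf confidence level (default 0.95).
#' @return List with `est`, `lwr`, `upr`, `n`.
#' @examples
#' ccc(1:10, 1:10 + rnorm(10, 0, 0.1))
#' @export
ccc <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("CCC requires n >= 3 complete pairs")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    stop("CCC undefined: both variables are constant with equal means")
  p <- 2 * sxy / denom
  # Lin (1989) variance of atanh(CCC); needs r and the scaled location shift u
  if (sx2 == 0 || sy2 == 0) {
    # degenerate: one variable constant; no sampling variance available
    return(list(est = p, lwr = NA_real_, upr = NA_real_, n = n))
  }
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^(1 / 4)
  if (abs(p) >= 1 || abs(r) < .Machine$double.eps^0.5) {
    ci <- c(NA_real_, NA_real_)
  } else {
    v <- ((1 - r^2) * p^2 / ((1 - p^2) * r^2) +
            2 * p^3 * (1 - p) * u^2 / (r * (1 - p^2)^2) -
            p^4 * u^4 / (2 * r^2 * (1 - p^2)^2)) / (n - 2)
    z <- atanh(p) + c(-1, 1) * stats::qnorm(1 - (1 - conf) / 2) * sqrt(max(v, 0))
    ci <- tanh(z)
  }
  list(est = p, lwr = ci[1], upr = ci[2], n = n)
}

#' Pearson correlation with Fisher-z 95% CI
#'
#' Sample correlation with the standard interval
#' `tanh(atanh(r) +/- z_{1-a/2} / sqrt(n - 3))`.
#'
#' @param x,y numeric vectors, `n >= 4`.
#' @param conf confidence level.
#' @return List with `est`, `lwr`, `upr`, `n`, and the two-sided `p_value`
#'   for the null of zero correlation.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("Pearson CI requires n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  r <- stats::cor(x, y)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (abs(r) < 1) tanh(atanh(r) + c(-1, 1) * zq / sqrt(n - 3)) else c(r, r)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.xmin))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(est = r, lwr = ci[1], upr = ci[2], n = n, p_value = p)
}

#' MAE and RMSE of paired measurements, with bootstrap CIs
#'
#' Mean absolute error and root-mean-square error of `x - y`, each with a
#' nonparametric case-resampling bootstrap percentile interval. Deterministic
#' given `seed`.
#'
#' @param x,y paired numeric vectors, `n >= 2`.
#' @param n_boot bootstrap replicates (default 2000); below 100 a warning is
#'   issued and the intervals should not be trusted.
#' @param seed integer seed for the resampling.
#' @param conf confidence level.
#' @return List with `mae` and `rmse`, each `(est, lwr, upr)`, plus `n` and
#'   `n_boot`.
#' @export
error_metrics <- function(x, y, n_boot = 2000, seed = 1, conf = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  d <- (x - y)[ok]
  n <- length(d)
  if (n < 2) stop("error metrics require n >= 2 complete pairs")
  if (n_boot < 100)
    warning("n_boot = ", n_boot, " is small; bootstrap CIs will be unstable")
  mae <- mean(abs(d)); rmse <- sqrt(mean(d^2))
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  bmae <- rowMeans(abs(matrix(d[idx], nrow = n_boot)))
  brmse <- sqrt(rowMeans(matrix(d[idx]^2, nrow = n_boot)))
  al <- (1 - conf) / 2
  qs <- function(v) unname(stats::quantile(v, c(al, 1 - al), type = 7))
  list(mae = list(est = mae, lwr = qs(bmae)[1], upr = qs(bmae)[2]),
       rmse = list(est = rmse, lwr = qs(brmse)[1], upr = qs(brmse)[2]),
       n = n, n_boot = n_boot)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `x - y`; by convention pass the automatic (AI)
#' measurement as `x` and the reference as `y`, so a positive bias means the
#' automatic method overestimates. Limits of agreement are
#' `bias +/- 1.96 sd(diff)` with the n-1 sample standard deviation and the
#' conventional fixed 1.96 multiplier. Proportional bias is assessed by
#' least-squares regression of the differences on the pair means.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return Object of class `fhoc_bland_altman`: list with `bias_mm`,
#'   `loa_low_mm`, `loa_high_mm`, `sd_diff_mm`, `pct_within_loa`,
#'   `prop_bias_slope`, `prop_bias_p`, `n`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Bland-Altman requires n >= 3 complete pairs")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  within <- 100 * mean(d >= loa[1] & d <= loa[2])
  if (stats::sd(m) > 0 && s > 0) {
    fit <- summary(stats::lm(d ~ m))$coefficients
    slope <- fit["m", "Estimate"]; slope_p <- fit["m", "Pr(>|t|)"]
  } else {
    slope <- 0; slope_p <- NA_real_
  }
  structure(list(bias_mm = bias, loa_low_mm = loa[1], loa_high_mm = loa[2],
                 sd_diff_mm = s, pct_within_loa = within,
                 prop_bias_slope = slope, prop_bias_p = slope_p, n = n),
            class = "fhoc_bland_altman")
}

#' @export
print.fhoc_bland_altman <- function(x, ...) {
  cat(sprintf(paste0("<fhoc_bland_altman> bias = %.3f mm, 95%% LoA [%.3f, %.3f] mm",
                     " (%.1f%% of %d pairs within)\n"),
              x$bias_mm, x$loa_low_mm, x$loa_high_mm, x$pct_within_loa, x$n))
  cat(sprintf("proportional bias slope = %.4f mm/mm (p = %.3g)\n",
              x$prop_bias_slope, x$prop_bias_p))
  invisible(x)
}

#' Paired t-test on two measurement vectors
#'
#' Thin wrapper around [stats::t.test()] with `paired = TRUE`, returning the
#' statistic and two-sided p-value.
#'
#' @param x,y paired numeric vectors, `n >= 2`.
#' @return List with `t`, `p_value`, `df`, `mean_diff`, `n`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("paired t-test requires n >= 2 complete pairs")
  if (stats::sd(x - y) == 0)
    stop("paired t-test undefined: differences have zero variance")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       n = length(x))
}

#' Fisher Z-test comparing two independent correlations
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' normal p-value.
#'
#' @param r1,r2 sample correlations, strictly inside (-1, 1).
#' @param n1,n2 group sizes, both `> 3`.
#' @return List with `z` and `p_value`.
#' @export
fisher_z <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("Fisher Z undefined for |r| = 1")
  if (n1 <= 3 || n2 <= 3) stop("Fisher Z requires n > 3 in both groups")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Agreement report for one stratum of paired measurements
#'
#' Bundles the full battery (CCC, Pearson r, MAE, RMSE, paired t, and
#' Bland-Altman) for one set of pairs. Strata with fewer than 3 pairs are
#' reported as insufficient rather than dropped.
#'
#' @param x,y paired numeric vectors (`x` = automatic, `y` = reference).
#' @param n_boot,seed bootstrap settings for the MAE/RMSE intervals.
#' @return One-row data.frame with columns `n`, `mean_x_mm`, `sd_x_mm`,
#'   `mean_y_mm`, `sd_y_mm`, `ccc`, `ccc_lwr`, `ccc_upr`, `r`, `r_lwr`,
#'   `r_upr`, `mae_mm`, `mae_lwr`, `mae_upr`, `rmse_mm`, `rmse_lwr`,
#'   `rmse_upr`, `paired_t_p`, `bias_mm`, `loa_low_mm`, `loa_high_mm`,
#'   `pct_within_loa`, `prop_bias_slope`, `prop_bias_p`, `insufficient`.
#' @export
agreement_report <- function(x, y, n_boot = 2000, seed = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  na_row <- data.frame(
    n = n, mean_x_mm = NA_real_, sd_x_mm = NA_real_, mean_y_mm = NA_real_,
    sd_y_mm = NA_real_, ccc = NA_real_, ccc_lwr = NA_real_, ccc_upr = NA_real_,
    r = NA_real_, r_lwr = NA_real_, r_upr = NA_real_, mae_mm = NA_real_,
    mae_lwr = NA_real_, mae_upr = NA_real_, rmse_mm = NA_real_,
    rmse_lwr = NA_real_, rmse_upr = NA_real_, paired_t_p = NA_real_,
    bias_mm = NA_real_, loa_low_mm = NA_real_, loa_high_mm = NA_real_,
    pct_within_loa = NA_real_, prop_bias_slope = NA_real_,
    prop_bias_p = NA_real_, insufficient = TRUE)
  if (n < 3) return(na_row)
  cc <- ccc(x, y)
  rr <- if (n >= 4 && stats::sd(x) > 0 && stats::sd(y) > 0)
    pearson_ci(x, y) else list(est = NA_real_, lwr = NA_real_, upr = NA_real_)
  em <- error_metrics(x, y, n_boot = n_boot, seed = seed)
  ba <- bland_altman(x, y)
  tp <- if (stats::sd(x - y) > 0) paired_t(x, y)$p_value else NA_real_
  data.frame(
    n = n, mean_x_mm = mean(x), sd_x_mm = stats::sd(x),
    mean_y_mm = mean(y), sd_y_mm = stats::sd(y),
    ccc = cc$est, ccc_lwr = cc$lwr, ccc_upr = cc$upr,
    r = rr$est, r_lwr = rr$lwr, r_upr = rr$upr,
    mae_mm = em$mae$est, mae_lwr = em$mae$lwr, mae_upr = em$mae$upr,
    rmse_mm = em$rmse$est, rmse_lwr = em$rmse$lwr, rmse_upr = em$rmse$upr,
    paired_t_p = tp,
    bias_mm = ba$bias_mm, loa_low_mm = ba$loa_low_mm,
    loa_high_mm = ba$loa_high_mm, pct_within_loa = ba$pct_within_loa,
    prop_bias_slope = ba$prop_bias_slope, prop_bias_p = ba$prop_bias_p,
    insufficient = FALSE)
}

#' Stratified agreement analysis of a measurement cohort
#'
#' Runs [agreement_report()] on a cohort table (columns `size_mm` =
#' automatic, `reference_mm` = reference) within strata defined by sex,
#' side, age bins, or their combinations. The stratum `"overall"` pools
#' everything. Strata with fewer than 3 pairs appear in the output flagged
#' `insufficient = TRUE`.
#'
#' @param cohort data.frame with at least `size_mm` and `reference_mm`,
#'   plus `sex`, `side`, `age_years` as required by `by`.
#' @param by character vector of stratifiers among `"sex"`, `"side"`,
#'   `"age"`; e.g. `c("sex", "age")` gives the per-sex age-subgroup design.
#'   `character(0)` (or `"overall"`) gives the pooled analysis only.
#' @param age_bins two-column matrix or data.frame of `[lo, hi)` bin edges in
#'   years; defaults to [default_age_bins()].
#' @param n_boot,seed bootstrap settings.
#' @return data.frame with one row per stratum: the stratifier columns
#'   (`stratum`, and `sex`/`side`/`age_bin` when used) followed by the
#'   [agreement_report()] columns.
#' @export
stratified_agreement <- function(cohort, by = c("sex"),
                                 age_bins = default_age_bins(),
                                 n_boot = 2000, seed = 1) {
  if (!all(c("size_mm", "reference_mm") %in% names(cohort)))
    stop("cohort must have `size_mm` and `reference_mm` columns")
  by <- setdiff(by, "overall")
  bad <- setdiff(by, c("sex", "side", "age"))
  if (length(bad))
    stop("unknown stratum key(s): ", paste(bad, collapse = ", "),
         " (valid: sex, side, age)")
  keys <- list()
  if ("sex" %in% by) keys$sex <- cohort$sex
  if ("side" %in% by) keys$side <- cohort$side
  if ("age" %in% by) {
    age_bins <- as.matrix(age_bins)
    lab <- rep(NA_character_, nrow(cohort))
    for (i in seq_len(nrow(age_bins))) {
      inbin <- cohort$age_years >= age_bins[i, 1] &
        (cohort$age_years < age_bins[i, 2] |
           (i == nrow(age_bins) & cohort$age_years <= age_bins[i, 2]))
      lab[inbin] <- sprintf("%g-%g", age_bins[i, 1], age_bins[i, 2])
    }
    keys$age_bin <- factor(lab, levels = sprintf("%g-%g", age_bins[, 1],
                                                 age_bins[, 2]))
  }
  run <- function(sel, info) {
    rep_row <- agreement_report(cohort$size_mm[sel], cohort$reference_mm[sel],
                                n_boot = n_boot, seed = seed)
    cbind(info, rep_row, row.names = NULL)
  }
  out <- run(rep(TRUE, nrow(cohort)), data.frame(stratum = "overall"))
  if (length(keys)) {
    grid <- expand.grid(lapply(keys, function(k) sort(unique(as.character(k)))),
                        stringsAsFactors = FALSE)
    names(grid) <- names(keys)
    for (i in seq_len(nrow(grid))) {
      sel <- rep(TRUE, nrow(cohort))
      for (k in names(keys))
        sel <- sel & !is.na(keys[[k]]) & as.character(keys[[k]]) == grid[i, k]
      info <- data.frame(stratum = paste(unlist(grid[i, , drop = FALSE]),
                                         collapse = "/"))
      info <- cbind(info, grid[i, , drop = FALSE], row.names = NULL)
      out_i <- run(sel, info)
      # align columns (overall row lacks the key columns)
      for (nm in setdiff(names(out_i), names(out))) out[[nm]] <- NA
      for (nm in setdiff(names(out), names(out_i))) out_i[[nm]] <- NA
      out <- rbind(out, out_i[names(out)])
    }
  }
  out
}
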