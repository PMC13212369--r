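utils::globalVariables(c("age_years", "size_mm", "percentile"))

#' Fit monotone polynomial quantile-regression growth curves
#'
#' For each sex and each quantile level, fits a degree-`degree` polynomial in
#' age minimizing the pinball (check) loss, subject to a non-decreasing
#' derivative at every age of a constraint grid (step `grid_step` years) --
#' the biologically-motivated constraint that reference growth curves must
#' not dip with age. The constrained problem is a linear program solved by
#' the package's interior-point pinball solver ([pinball_fit()]); the
#' monotonicity constraints enter as exact-penalty rows whose weight is
#' escalated until the fitted derivative is nonnegative to within 1e-7 of
#' the data scale. Predicted quantiles are rearranged (sorted across levels
#' per age) at evaluation time, so reported percentile sets never cross.
#' Ages are internally rescaled to `[-1, 1]` for numerical conditioning;
#' the fit is deterministic.
#'
#' @param cohort data.frame with `age_years`, `sex`, `size_mm` (one row per
#'   hip; pass a per-child aggregate yourself if a per-child analysis is
#'   wanted).
#' @param taus quantile levels; default the seven reference levels
#'   0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95.
#' @param degree polynomial degree (default 3).
#' @param grid_step spacing (years) of the monotonicity-constraint grid.
#' @param age_domain `[min, max]` ages (years) over which the curves are
#'   defined, constrained, and may be evaluated; defaults to each sex's
#'   observed age range. Supply e.g. `c(0.5, 11)` to pin the reference
#'   domain to the study design rather than the realized sample.
#' @return Object of class `fhoc_growth_chart`: a list of per-sex
#'   `fhoc_quantile_model` objects (each with `coefficients` -- a
#'   `(degree+1) x length(taus)` matrix in the rescaled basis -- `taus`,
#'   `degree`, `age_domain`, `age_center`, `age_half`, `constraint_grid`,
#'   `n`, `sex`).
#' @examples
#' co <- gen_cohort(generator_config(n_per_sex_per_agegroup = 10, seed = 3))
#' ch <- fit_quantile_curves(co, taus = c(0.05, 0.5, 0.95), degree = 2)
#' predict_percentiles(ch, ages = c(1, 5, 10))
#' @export
fit_quantile_curves <- function(cohort,
                                taus = c(0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95),
                                degree = 3, grid_step = 0.25,
                                age_domain = NULL) {
  stopifnot(all(c("age_years", "sex", "size_mm") %in% names(cohort)))
  if (any(taus <= 0 | taus >= 1)) stop("taus must be inside (0, 1)")
  taus <- sort(taus)
  sexes <- sort(unique(as.character(cohort$sex)))
  models <- lapply(sexes, function(s) {
    sub <- cohort[cohort$sex == s & is.finite(cohort$size_mm), ]
    .fit_one_sex(sub$age_years, sub$size_mm, s, taus, degree, grid_step,
                 age_domain)
  })
  names(models) <- sexes
  structure(list(models = models, taus = taus, degree = degree,
                 grid_step = grid_step),
            class = "fhoc_growth_chart")
}

.fit_one_sex <- function(age, y, sex, taus, degree, grid_step,
                         age_domain = NULL) {
  n <- length(y)
  if (n < degree + 1)
    stop("sex ", sex, ": ", n, " points cannot identify ", degree + 1,
         " polynomial coefficients")
  if (length(unique(age)) < degree + 2)
    stop("sex ", sex, ": need at least ", degree + 2, " distinct ages")
  if (any(y <= 0)) stop("sex ", sex, ": sizes must be positive")
  dom <- if (is.null(age_domain)) range(age) else sort(age_domain[1:2])
  center <- mean(dom); half <- max(diff(dom) / 2, .Machine$double.eps)
  tt <- (age - center) / half
  X <- outer(tt, 0:degree, `^`)
  grid_age <- unique(c(seq(dom[1], dom[2], by = grid_step), dom[2]))
  tg <- (grid_age - center) / half
  D <- outer(tg, 0:degree, function(t, k) k * t^pmax(k - 1, 0))
  D[, 1] <- 0                              # intercept has no derivative
  nonzero <- rowSums(abs(D)) > 0
  D <- D[nonzero, , drop = FALSE]
  grid_used <- grid_age[nonzero]
  m <- nrow(D)
  tol <- 1e-7 * max(1, max(abs(y)))

  coefs <- matrix(NA_real_, degree + 1, length(taus),
                  dimnames = list(paste0("c", 0:degree), paste0("tau", taus)))
  for (j in seq_along(taus)) {
    tau <- taus[j]
    lambda <- 10 * max(n, 100)
    for (esc in 1:4) {
      if (m > 0) {
        fit <- pinball_fit(rbind(X, D), c(y, rep(0, m)),
                           wpos = c(rep(tau, n), rep(lambda, m)),
                           wneg = c(rep(1 - tau, n), rep(0, m)))
      } else {
        fit <- pinball_fit(X, y, tau, 1 - tau)
      }
      beta <- fit$beta
      viol <- if (m > 0) -min(drop(D %*% beta)) else 0
      if (viol <= tol) break
      lambda <- lambda * 10
    }
    if (viol > tol)
      stop("sex ", sex, ", tau ", tau,
           ": monotonicity constraints could not be satisfied; binding ages: ",
           paste(round(grid_used[drop(D %*% beta) < -tol], 2), collapse = ", "))
    coefs[, j] <- beta
  }
  structure(list(sex = sex, taus = taus, degree = degree,
                 coefficients = coefs, age_domain = dom,
                 age_center = center, age_half = half,
                 constraint_grid = grid_used, n = n),
            class = "fhoc_quantile_model")
}

#' @export
print.fhoc_quantile_model <- function(x, ...) {
  cat(sprintf("<fhoc_quantile_model> sex=%s degree=%d taus=%s ages %.2f-%.2f (n=%d)\n",
              x$sex, x$degree, paste(x$taus, collapse = ","),
              x$age_domain[1], x$age_domain[2], x$n))
  invisible(x)
}

#' @export
print.fhoc_growth_chart <- function(x, ...) {
  cat("<fhoc_growth_chart>\n")
  for (m in x$models) print(m)
  invisible(x)
}

# raw (un-rearranged) quantile predictions: length(ages) x length(taus)
.predict_raw <- function(model, ages) {
  tt <- (ages - model$age_center) / model$age_half
  X <- outer(tt, 0:model$degree, `^`)
  X %*% model$coefficients
}

# rearranged predictions (sorted across taus per age => non-crossing)
.predict_rearranged <- function(model, ages) {
  P <- .predict_raw(model, ages)
  if (ncol(P) > 1) P[] <- t(apply(P, 1, sort))
  P
}

.check_domain <- function(model, ages) {
  lo <- model$age_domain[1]; hi <- model$age_domain[2]
  bad <- ages < lo - 1e-9 | ages > hi + 1e-9
  if (any(bad))
    stop("age(s) ", paste(round(ages[bad], 3), collapse = ", "),
         " outside the fitted domain [", round(lo, 3), ", ", round(hi, 3),
         "]; reference values are not extrapolated")
}

#' Percentile reference table from fitted growth curves
#'
#' Evaluates the rearranged quantile curves at the requested ages. Ages
#' outside the fitted domain raise an error (reference values are never
#' extrapolated).
#'
#' @param model an `fhoc_growth_chart` (both sexes) or a single
#'   `fhoc_quantile_model`.
#' @param ages evaluation ages in years; default 0.5 and 1-11.
#' @return data.frame with `sex`, `age_years`, and one `q<level>_mm` column
#'   per fitted quantile level (e.g. `q5_mm`, `q50_mm`, `q95_mm`).
#' @export
predict_percentiles <- function(model, ages = c(0.5, 1:11)) {
  if (inherits(model, "fhoc_growth_chart")) {
    out <- do.call(rbind, lapply(model$models, predict_percentiles, ages = ages))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(model, "fhoc_quantile_model"))
  .check_domain(model, ages)
  P <- .predict_rearranged(model, ages)
  colnames(P) <- sprintf("q%g_mm", 100 * model$taus)
  out <- data.frame(sex = model$sex, age_years = ages, P,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percentile of a measured size at a given age
#'
#' Locates a size on the fitted reference chart by monotone interpolation
#' across the fitted quantile levels. Sizes below the lowest or above the
#' highest fitted percentile are flagged, not extrapolated.
#'
#' @param model a single-sex `fhoc_quantile_model`, or an
#'   `fhoc_growth_chart` plus `sex`.
#' @param age age in years (within the fitted domain).
#' @param size_mm measured size in mm.
#' @param sex required when `model` is a chart of both sexes.
#' @return List with `percentile` (0-100, `NA` when out of range) and `flag`
#'   (`"ok"`, `"<5"`, or `">95"` -- the labels use the extreme fitted
#'   levels).
#' @export
percentile_of <- function(model, age, size_mm, sex = NULL) {
  if (inherits(model, "fhoc_growth_chart")) {
    if (is.null(sex) || !sex %in% names(model$models))
      stop("specify `sex` (one of: ",
           paste(names(model$models), collapse = ", "), ")")
    model <- model$models[[sex]]
  }
  stopifnot(inherits(model, "fhoc_quantile_model"), length(age) == 1)
  .check_domain(model, age)
  qv <- drop(.predict_rearranged(model, age))
  tv <- 100 * model$taus
  lo_lab <- sprintf("<%g", min(tv)); hi_lab <- sprintf(">%g", max(tv))
  if (size_mm < min(qv)) return(list(percentile = NA_real_, flag = lo_lab))
  if (size_mm > max(qv)) return(list(percentile = NA_real_, flag = hi_lab))
  # collapse exactly-flat segments so interpolation is well defined
  keep <- !duplicated(qv)
  pct <- stats::approx(qv[keep], tv[keep], xout = size_mm,
                       ties = "ordered")$y
  list(percentile = as.numeric(pct), flag = "ok")
}

#' Adjusted R-squared of the fitted median growth curve
#'
#' Coefficient of determination of the (rearranged) median curve against the
#' observed sizes, adjusted for the polynomial degree:
#' `1 - (1 - R2)(n - 1)/(n - p - 1)` with `p = degree`.
#'
#' @param model `fhoc_growth_chart` or `fhoc_quantile_model`.
#' @param cohort cohort data.frame (rows of other sexes are ignored for a
#'   single-sex model).
#' @return Named numeric vector, one value per sex.
#' @export
adjusted_r2 <- function(model, cohort) {
  if (inherits(model, "fhoc_growth_chart")) {
    vals <- vapply(model$models, adjusted_r2, numeric(1), cohort = cohort)
    names(vals) <- names(model$models)
    return(vals)
  }
  stopifnot(inherits(model, "fhoc_quantile_model"))
  if (!0.5 %in% model$taus) stop("model has no fitted median curve")
  sub <- cohort[as.character(cohort$sex) == model$sex &
                  is.finite(cohort$size_mm), ]
  n <- nrow(sub)
  p <- model$degree
  if (n < p + 3) stop("need at least degree + 3 observations")
  med_col <- which(model$taus == 0.5)
  pred <- .predict_rearranged(model, sub$age_years)[, med_col]
  sse <- sum((sub$size_mm - pred)^2)
  sst <- sum((sub$size_mm - mean(sub$size_mm))^2)
  if (sst == 0) stop("zero total variance: R-squared undefined")
  r2 <- 1 - sse / sst
  unname(1 - (1 - r2) * (n - 1) / (n - p - 1))
}

#' Prediction errors of the median growth curve by age bin
#'
#' In-sample residuals of the observed sizes against the fitted median
#' curve, summarized per age bin as MAE and RMSE with nonparametric
#' bootstrap percentile CIs. Empty bins are reported with `n = 0` and `NA`
#' errors rather than dropped.
#'
#' @param model `fhoc_growth_chart` or single-sex `fhoc_quantile_model`.
#' @param cohort cohort data.frame.
#' @param bins 2-column `[lo, hi)` matrix of age bins; default
#'   [default_age_bins()].
#' @param n_boot,seed bootstrap settings (see [error_metrics()]).
#' @return data.frame with `sex`, `age_bin`, `bin_lo_years`, `bin_hi_years`,
#'   `n`, `mae_mm`, `mae_lwr`, `mae_upr`, `rmse_mm`, `rmse_lwr`, `rmse_upr`.
#' @export
group_errors <- function(model, cohort, bins = default_age_bins(),
                         n_boot = 2000, seed = 1) {
  if (inherits(model, "fhoc_growth_chart")) {
    out <- do.call(rbind, lapply(model$models, group_errors, cohort = cohort,
                                 bins = bins, n_boot = n_boot, seed = seed))
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(model, "fhoc_quantile_model"))
  if (!0.5 %in% model$taus) stop("model has no fitted median curve")
  bins <- as.matrix(bins)
  sub <- cohort[as.character(cohort$sex) == model$sex &
                  is.finite(cohort$size_mm), ]
  med_col <- which(model$taus == 0.5)
  inside <- sub$age_years >= model$age_domain[1] - 1e-9 &
    sub$age_years <= model$age_domain[2] + 1e-9
  sub <- sub[inside, ]
  resid <- sub$size_mm -
    .predict_rearranged(model, sub$age_years)[, med_col]
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    last <- i == nrow(bins)
    sel <- sub$age_years >= bins[i, 1] &
      (sub$age_years < bins[i, 2] | (last & sub$age_years <= bins[i, 2]))
    base <- data.frame(sex = model$sex,
                       age_bin = sprintf("%g-%g", bins[i, 1], bins[i, 2]),
                       bin_lo_years = bins[i, 1], bin_hi_years = bins[i, 2],
                       n = sum(sel), mae_mm = NA_real_, mae_lwr = NA_real_,
                       mae_upr = NA_real_, rmse_mm = NA_real_,
                       rmse_lwr = NA_real_, rmse_upr = NA_real_,
                       stringsAsFactors = FALSE)
    if (sum(sel) >= 2) {
      em <- error_metrics(resid[sel], rep(0, sum(sel)), n_boot = n_boot,
                          seed = seed)
      base$mae_mm <- em$mae$est; base$mae_lwr <- em$mae$lwr
      base$mae_upr <- em$mae$upr
      base$rmse_mm <- em$rmse$est; base$rmse_lwr <- em$rmse$lwr
      base$rmse_upr <- em$rmse$upr
    } else if (sum(sel) == 1) {
      base$mae_mm <- abs(resid[sel]); base$rmse_mm <- abs(resid[sel])
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot fitted growth curves with raw measurements
#'
#' One panel per sex: the fitted (rearranged) percentile curves over the age
#' domain, with the cohort's raw sizes as points.
#'
#' @param chart an `fhoc_growth_chart`.
#' @param cohort optional cohort data.frame for the point overlay.
#' @param step curve evaluation step in years.
#' @return A ggplot object.
#' @export
plot_growth_chart <- function(chart, cohort = NULL, step = 0.05) {
  stopifnot(inherits(chart, "fhoc_growth_chart"))
  curves <- do.call(rbind, lapply(chart$models, function(m) {
    ages <- seq(m$age_domain[1], m$age_domain[2], by = step)
    P <- .predict_rearranged(m, ages)
    do.call(rbind, lapply(seq_along(m$taus), function(j) {
      data.frame(sex = m$sex, age_years = ages,
                 percentile = sprintf("P%g", 100 * m$taus[j]),
                 size_mm = P[, j], stringsAsFactors = FALSE)
    }))
  }))
  lev <- sprintf("P%g", 100 * chart$taus)
  curves$percentile <- factor(curves$percentile, levels = lev)
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = age_years, y = size_mm))
  if (!is.null(cohort))
    p <- p + ggplot2::geom_point(data = cohort, colour = "grey60",
                                 size = 0.4, alpha = 0.5)
  p + ggplot2::geom_line(ggplot2::aes(colour = percentile)) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Age (years)", y = "FHOC size (mm)",
                  colour = "Percentile") +
    ggplot2::theme_minimal()
}
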