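#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`. Defined as 1 when both masks are empty
#' (perfect agreement on absence).
#'
#' @param a,b [fhoc_mask()] objects or binary matrices of equal dimensions.
#' @return Scalar in `[0, 1]`.
#' @examples
#' a <- matrix(FALSE, 10, 10); a[3:6, 3:8] <- TRUE
#' dice(a, a)  # 1
#' @export
dice <- function(a, b) {
  pa <- if (inherits(a, "fhoc_mask")) a$pixels else a > 0
  pb <- if (inherits(b, "fhoc_mask")) b$pixels else b > 0
  if (!identical(dim(pa), dim(pb)))
    stop("mask shapes differ: ", paste(dim(pa), collapse = "x"),
         " vs ", paste(dim(pb), collapse = "x"))
  na <- sum(pa); nb <- sum(pb)
  if (na + nb == 0L) return(1)
  2 * sum(pa & pb) / (na + nb)
}

# min distance from each point in p (n x 2) to the set q (m x 2)
.min_dists <- function(p, q) {
  vapply(seq_len(nrow(p)), function(i) {
    sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
  }, numeric(1))
}

#' Hausdorff distance between two mask boundaries, in millimetres
#'
#' Exact (100th percentile) symmetric Hausdorff distance between the boundary
#' point sets of two masks, scaled by the pixel spacing. Boundaries are
#' foreground pixels with at least one background 4-neighbour.
#'
#' @param a,b [fhoc_mask()] objects or binary matrices (then `spacing_mm`
#'   is required); both must be non-empty.
#' @param spacing_mm mm per pixel; defaults to the masks' spacing, which must
#'   agree between the two.
#' @return Scalar distance in mm.
#' @export
hausdorff <- function(a, b, spacing_mm = NULL) {
  if (is.null(spacing_mm)) {
    if (!inherits(a, "fhoc_mask") || !inherits(b, "fhoc_mask"))
      stop("`spacing_mm` is required for plain-matrix masks")
    if (!isTRUE(all.equal(a$spacing_mm, b$spacing_mm)))
      stop("masks have different spacing")
    spacing_mm <- a$spacing_mm
  }
  pa <- if (inherits(a, "fhoc_mask")) a$pixels else a > 0
  pb <- if (inherits(b, "fhoc_mask")) b$pixels else b > 0
  if (!identical(dim(pa), dim(pb))) stop("mask shapes differ")
  if (!any(pa) || !any(pb))
    stop("Hausdorff distance requires two non-empty masks")
  ba <- boundary_coords(pa)
  bb <- boundary_coords(pb)
  d_ab <- max(.min_dists(ba, bb))
  d_ba <- max(.min_dists(bb, ba))
  max(d_ab, d_ba) * spacing_mm
}

#' Landmark localization errors: MRE and successful detection rates
#'
#' Per-case radial error is the Euclidean distance between predicted and true
#' landmark, scaled to mm. The mean radial error (MRE) is their mean; the
#' successful detection rate SDR(t) is the percentage of cases with error
#' `<= t`, reported at the conventional thresholds 1, 2, 2.5, 3 and 4 mm.
#'
#' @param pred,truth n x 2 matrices of `(row, col)` pixel coordinates (or
#'   lists of length-2 points), paired by index.
#' @param spacing_mm mm per pixel.
#' @param thresholds_mm thresholds at which SDR is evaluated.
#' @return Object of class `fhoc_sdr`: list with `per_case_errors_mm`,
#'   `mre_mm`, `thresholds_mm`, `rates_pct`.
#' @examples
#' p <- rbind(c(0, 0), c(10, 0)); t <- rbind(c(0, 0), c(10, 5))
#' radial_errors(p, t, spacing_mm = 0.2)
#' @export
radial_errors <- function(pred, truth, spacing_mm,
                          thresholds_mm = c(1, 2, 2.5, 3, 4)) {
  to_mat <- function(x) {
    if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
    as.matrix(x)
  }
  p <- to_mat(pred); t <- to_mat(truth)
  if (nrow(p) != nrow(t))
    stop("pred and truth have different lengths: ", nrow(p), " vs ", nrow(t))
  if (spacing_mm <= 0) stop("`spacing_mm` must be positive")
  err <- sqrt(rowSums((p - t)^2)) * spacing_mm
  rates <- vapply(thresholds_mm, function(th) 100 * mean(err <= th), numeric(1))
  structure(list(per_case_errors_mm = err,
                 mre_mm = mean(err),
                 thresholds_mm = thresholds_mm,
                 rates_pct = rates),
            class = "fhoc_sdr")
}

#' @export
print.fhoc_sdr <- function(x, ...) {
  cat(sprintf("<fhoc_sdr> n = %d, MRE = %.3f mm\n",
              length(x$per_case_errors_mm), x$mre_mm))
  cat(paste(sprintf("SDR <=%g mm: %.1f%%", x$thresholds_mm, x$rates_pct),
            collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate predicted against reference masks, case by case
#'
#' Convenience wrapper producing a per-case table of Dice and Hausdorff
#' values for paired lists of masks.
#'
#' @param pred,truth lists of [fhoc_mask()] (paired by index or by name).
#' @param spacing_mm mm per pixel.
#' @return data.frame with columns `case`, `dice`, `hausdorff_mm`.
#' @export
evaluate_segmentation <- function(pred, truth, spacing_mm) {
  if (!is.null(names(pred)) && !is.null(names(truth)))
    truth <- truth[names(pred)]
  if (length(pred) != length(truth)) stop("pred/truth length mismatch")
  nm <- names(pred)
  if (is.null(nm)) nm <- as.character(seq_along(pred))
  out <- data.frame(case = nm,
                    dice = NA_real_, hausdorff_mm = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pred)) {
    out$dice[i] <- dice(pred[[i]], truth[[i]])
    out$hausdorff_mm[i] <- hausdorff(pred[[i]], truth[[i]], spacing_mm)
  }
  out
}
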