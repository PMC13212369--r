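#' Binary segmentation mask with isotropic pixel spacing
#'
#' Container for a 2-D binary mask in image convention: row 1 of the matrix is
#' the top image row, column 1 the left image column. Coordinates reported by
#' the measurement functions are 0-based `(row, col)` with pixel centers at
#' integer positions. Spacing is isotropic (mm per pixel); anisotropic inputs
#' are rejected rather than silently averaged.
#'
#' @param pixels logical or 0/1 numeric matrix; `TRUE`/nonzero is foreground.
#' @param spacing_mm positive scalar, millimetres per pixel. A length-2 vector
#'   is accepted only when both entries are equal.
#' @return An object of class `fhoc_mask`: a list with elements `pixels`
#'   (logical matrix) and `spacing_mm` (scalar).
#' @examples
#' m <- fhoc_mask(matrix(c(0, 1, 1, 0), 2, 2), spacing_mm = 0.2)
#' sum(m$pixels)
#' @export
fhoc_mask <- function(pixels, spacing_mm) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (length(spacing_mm) == 2L) {
    if (!isTRUE(all.equal(spacing_mm[1], spacing_mm[2])))
      stop("anisotropic pixel spacing is not supported; got ",
           spacing_mm[1], " x ", spacing_mm[2], " mm")
    spacing_mm <- spacing_mm[1]
  }
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  storage.mode(pixels) <- "logical"
  pixels[is.na(pixels)] <- FALSE
  structure(list(pixels = pixels, spacing_mm = as.numeric(spacing_mm)),
            class = "fhoc_mask")
}

#' @export
print.fhoc_mask <- function(x, ...) {
  cat(sprintf("<fhoc_mask> %d x %d px, spacing %.4g mm/px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm, sum(x$pixels)))
  invisible(x)
}

as_mask <- function(x, spacing_mm = NULL) {
  if (inherits(x, "fhoc_mask")) {
    if (!is.null(spacing_mm)) x$spacing_mm <- spacing_mm
    return(x)
  }
  if (is.null(spacing_mm))
    stop("`spacing_mm` is required when the mask is a plain matrix")
  fhoc_mask(x, spacing_mm)
}

#' Read / write masks as 8-bit PNG
#'
#' Masks are stored as single-channel 8-bit PNG with 0 = background and
#' 255 = foreground. On read, any pixel with intensity > 0.5 (after png's
#' 0-1 scaling) is foreground; of multi-channel files the first channel
#' is used.
#'
#' @param path file path.
#' @param spacing_mm mm per pixel of the stored image (PNG carries no spacing).
#' @param mask an [fhoc_mask()].
#' @return `read_mask()` returns an [fhoc_mask()]; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, spacing_mm) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  fhoc_mask(img > 0.5, spacing_mm)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  px <- if (inherits(mask, "fhoc_mask")) mask$pixels else mask
  png::writePNG(ifelse(px, 1, 0), target = path)
  invisible(path)
}

# 8-connected component labelling by row runs + union-find.
# Returns list(labels = integer matrix (0 = background), n = component count).
# Run-based: runs of consecutive foreground pixels within each row are the
# union-find nodes; runs in adjacent rows merge when their column ranges
# touch or overlap diagonally ([start-1, end+1]).
label_components <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  labels <- matrix(0L, nr, nc)
  if (!any(px)) return(list(labels = labels, n = 0L))

  # collect runs per row
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (i in seq_len(nr)) {
    v <- px[i, ]
    if (!any(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      run_row <- c(run_row, rep.int(i, sum(keep)))
      run_s <- c(run_s, starts[keep])
      run_e <- c(run_e, ends[keep])
    }
  }
  nruns <- length(run_row)
  parent <- seq_len(nruns)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  # runs are generated in row-major order; per-row index ranges
  row_first <- match(seq_len(nr), run_row)
  row_count <- tabulate(run_row, nbins = nr)
  # link each run to touching/overlapping runs in the previous row
  # (8-connectivity: column ranges expanded by one)
  for (k in seq_len(nruns)) {
    i <- run_row[k]
    if (i == 1L || row_count[i - 1L] == 0L) next
    prev <- seq.int(row_first[i - 1L], length.out = row_count[i - 1L])
    for (j in prev) {
      if (run_e[j] < run_s[k] - 1L) next
      if (run_s[j] > run_e[k] + 1L) break
      ra <- find(j); rb <- find(k)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nruns), find, integer(1))
  comp <- match(roots, unique(roots))
  for (k in seq_len(nruns))
    labels[run_row[k], run_s[k]:run_e[k]] <- comp[k]
  list(labels = labels, n = max(comp))
}

#' Keep only the largest 8-connected foreground component
#'
#' Robustness step for predicted masks that may contain speckle: all but the
#' largest 8-connected component are removed. Area ties are broken
#' deterministically in favour of the component containing the smallest
#' `(row, col)` pixel in lexicographic order. The number of components found
#' in the input is recorded in the `n_components_found` attribute.
#'
#' @param mask an [fhoc_mask()] (or matrix plus `spacing_mm`).
#' @param spacing_mm spacing, required only when `mask` is a plain matrix.
#' @return An [fhoc_mask()] with a single foreground component and attribute
#'   `n_components_found`.
#' @export
largest_component <- function(mask, spacing_mm = NULL) {
  mask <- as_mask(mask, spacing_mm)
  if (!any(mask$pixels))
    stop("no ossification center: mask has no foreground pixels ",
         "(the FHOC may not have appeared yet)")
  lab <- label_components(mask$pixels)
  if (lab$n > 1L) {
    areas <- tabulate(lab$labels[lab$labels > 0L], nbins = lab$n)
    best <- which(areas == max(areas))
    if (length(best) > 1L) {
      # lexicographic (row, col) of each tied component's first pixel
      first_key <- vapply(best, function(b) {
        idx <- which(lab$labels == b, arr.ind = TRUE)
        key <- idx[, 1] * (ncol(mask$pixels) + 1) + idx[, 2]
        min(key)
      }, numeric(1))
      best <- best[which.min(first_key)]
    }
    mask$pixels <- lab$labels == best
  }
  attr(mask, "n_components_found") <- lab$n
  mask
}

# boundary = foreground pixels with at least one background 4-neighbour
# (image border counts as background)
boundary_pixels <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  up    <- rbind(FALSE, px[-nr, , drop = FALSE])
  down  <- rbind(px[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, px[, -nc, drop = FALSE])
  right <- cbind(px[, -1, drop = FALSE], FALSE)
  px & !(up & down & left & right)
}

# boundary coordinates, 0-based (row, col) matrix
boundary_coords <- function(px) {
  idx <- which(boundary_pixels(px), arr.ind = TRUE)
  cbind(row = idx[, 1] - 1, col = idx[, 2] - 1)
}
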