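#' Detect medial and lateral cortical landmarks on an FHOC mask
#'
#' The FHOC size is the maximum transverse diameter: the chord from the medial
#' margin to the outermost lateral point of the ossified femoral head. On an
#' anteroposterior radiograph both landmarks are horizontal extremes of the
#' segmented region, so the candidate landmarks are the boundary pixels
#' attaining the minimal and maximal column index. When several boundary
#' pixels share an extreme column, the pixel whose row is closest to the
#' foreground centroid row is chosen (ties broken toward the smaller row).
#'
#' Which extreme is "medial" depends on the hip: on an AP view the patient's
#' right hip appears on the image left, so for `side = "right"` the min-column
#' point is the lateral landmark; for `side = "left"` it is the medial one.
#' With `side = "unknown"` the points are labelled by image position only.
#'
#' @param mask a single-component [fhoc_mask()] (use [largest_component()]
#'   first if the mask may contain speckle).
#' @param side `"left"`, `"right"`, or `"unknown"`.
#' @param spacing_mm spacing, required only when `mask` is a plain matrix.
#' @return An object of class `fhoc_landmarks`: list with `medial` and
#'   `lateral` (each a named numeric `(row, col)`, 0-based pixel-center
#'   coordinates) and `side`.
#' @examples
#' px <- matrix(FALSE, 21, 31); px[8:14, 6:26] <- TRUE
#' detect_landmarks(fhoc_mask(px, 0.2), side = "left")
#' @export
detect_landmarks <- function(mask, side = c("unknown", "left", "right"),
                             spacing_mm = NULL) {
  side <- match.arg(side)
  mask <- as_mask(mask, spacing_mm)
  px <- mask$pixels
  if (!any(px))
    stop("no ossification center: mask has no foreground pixels")
  lab <- label_components(px)
  if (lab$n > 1L)
    stop("mask has ", lab$n, " connected components; ",
         "apply largest_component() before landmark detection")

  fg <- which(px, arr.ind = TRUE)
  centroid_row <- mean(fg[, 1])
  pick <- function(col_target) {
    rows <- unname(fg[fg[, 2] == col_target, 1])
    # all pixels in an extreme column are boundary pixels
    r <- rows[order(abs(rows - centroid_row), rows)][1]
    c(row = r - 1, col = col_target - 1)
  }
  p_min <- pick(min(fg[, 2]))
  p_max <- pick(max(fg[, 2]))

  if (side == "right") {
    medial <- p_max; lateral <- p_min
  } else {
    # left hip, or unknown: image-left point reported first/medial slot
    medial <- p_min; lateral <- p_max
  }
  structure(list(medial = medial, lateral = lateral, side = side),
            class = "fhoc_landmarks")
}

#' @export
print.fhoc_landmarks <- function(x, ...) {
  cat(sprintf("<fhoc_landmarks> side=%s medial=(%.1f, %.1f) lateral=(%.1f, %.1f)\n",
              x$side, x$medial["row"], x$medial["col"],
              x$lateral["row"], x$lateral["col"]))
  invisible(x)
}

#' Chord length between two landmarks, in millimetres
#'
#' @param pair an `fhoc_landmarks` object, or a list with `medial` and
#'   `lateral` numeric `(row, col)` points.
#' @param spacing_mm positive mm-per-pixel scalar.
#' @return Euclidean distance between the landmarks times the spacing (mm).
#' @examples
#' p <- list(medial = c(row = 100, col = 50), lateral = c(row = 100, col = 150))
#' measure_size(p, spacing_mm = 0.2)  # 20 mm
#' @export
measure_size <- function(pair, spacing_mm) {
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  d <- sqrt(sum((pair$medial - pair$lateral)^2))
  as.numeric(d * spacing_mm)
}

#' Measure FHOC size from a segmentation mask
#'
#' Full stage-3 post-processing: keep the largest 8-connected component,
#' detect the medial/lateral landmarks, and compute the size as the chord
#' length between them.
#'
#' @inheritParams detect_landmarks
#' @return An object of class `fhoc_measurement`: list with `size_mm`,
#'   `landmarks` (the [detect_landmarks()] result), `n_components_found`,
#'   `spacing_mm`.
#' @examples
#' px <- matrix(FALSE, 41, 61); px[11:31, 11:51] <- TRUE
#' measure_mask(fhoc_mask(px, 0.2), side = "left")
#' @export
measure_mask <- function(mask, side = c("unknown", "left", "right"),
                         spacing_mm = NULL) {
  side <- match.arg(side)
  mask <- as_mask(mask, spacing_mm)
  clean <- largest_component(mask)
  lm <- detect_landmarks(clean, side = side)
  structure(list(size_mm = measure_size(lm, clean$spacing_mm),
                 landmarks = lm,
                 n_components_found = attr(clean, "n_components_found"),
                 spacing_mm = clean$spacing_mm),
            class = "fhoc_measurement")
}

#' @export
print.fhoc_measurement <- function(x, ...) {
  cat(sprintf("<fhoc_measurement> size = %.3f mm (side %s, %d component%s found)\n",
              x$size_mm, x$landmarks$side, x$n_components_found,
              if (x$n_components_found == 1L) "" else "s"))
  invisible(x)
}

#' Measure a directory of mask PNGs into a cohort-compatible table
#'
#' Batch mode over `*.png` files. File names of the form
#' `<child_id>_<side>.png` (side `left`/`right`/`L`/`R`) have the side parsed
#' from the name; anything else is measured with `side = "unknown"`.
#'
#' @param dir directory of mask PNGs.
#' @param spacing_mm mm per pixel (shared by all masks).
#' @return data.frame with columns `file`, `child_id`, `side`, `size_mm`,
#'   `n_components_found`.
#' @export
measure_mask_dir <- function(dir, spacing_mm) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop("no .png masks found in ", dir)
  rows <- lapply(files, function(f) {
    stem <- sub("\\.png$", "", basename(f))
    side <- "unknown"; id <- stem
    m <- regmatches(stem, regexec("^(.*)_(left|right|L|R)$", stem))[[1]]
    if (length(m) == 3L) {
      id <- m[2]
      side <- c(left = "left", right = "right", L = "left", R = "right")[m[3]]
    }
    res <- measure_mask(read_mask(f, spacing_mm), side = side)
    data.frame(file = basename(f), child_id = id, side = side,
               size_mm = res$size_mm,
               n_components_found = res$n_components_found,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
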