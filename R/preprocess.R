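#' Pre-processing configuration
#'
#' Parameters of the five-step segmentation: binarization, inversion
#' (polarity normalization), morphological cleaning, hole-filling with
#' small-component removal, and background removal.
#'
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold gray-level threshold in `[0,1]`; required when
#'   `threshold_method = "fixed"`.
#' @param structuring_element_radius disc radius (pixels, >= 1) for the
#'   opening/closing step.
#' @param min_component_area components smaller than this many pixels are
#'   discarded; `NULL` (default) means 0.1% of the image area.
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(threshold_method = c("otsu", "fixed"),
                              fixed_threshold = NULL,
                              structuring_element_radius = 2L,
                              min_component_area = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (threshold_method == "fixed") {
    if (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 1)
      stop("fixed_threshold in [0,1] is required for threshold_method='fixed'")
  }
  stopifnot(structuring_element_radius >= 1)
  if (!is.null(min_component_area)) stopifnot(min_component_area >= 0)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 structuring_element_radius =
                   as.integer(structuring_element_radius),
                 min_component_area = min_component_area),
            class = "preprocess_config")
}

# BT.601 luma of an H x W x 3 array
.gray_level <- function(img) {
  0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3]
}

.check_rgb <- function(img) {
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3))
    stop("expected an H x W x 3 RGB array")
  if (min(img) < -1e-12 || max(img) > 1 + 1e-12)
    stop("RGB values must lie in [0,1]")
  invisible(img)
}

#' Binarize an RGB image by gray-level thresholding
#'
#' Thresholds the BT.601 gray level; pixels brighter than the threshold
#' (the white background) map to `TRUE`. The threshold is Otsu's, computed
#' on a 256-bin histogram, or a fixed value.
#'
#' @param img H x W x 3 array in `[0,1]`.
#' @param cfg a [preprocess_config()].
#' @return Logical H x W matrix.
#' @export
binarize <- function(img, cfg = preprocess_config()) {
  .check_rgb(img)
  g <- .gray_level(img)
  if (cfg$threshold_method == "otsu") {
    if (max(g) - min(g) < 1e-12)
      stop("degenerate histogram: constant image, Otsu threshold undefined")
    th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1), levels = 256)
  } else {
    th <- cfg$fixed_threshold
  }
  g > th
}

#' Logical inversion of a binary image
#'
#' @param b logical matrix.
#' @return Negated logical matrix (involutive).
#' @export
invert_binary <- function(b) {
  stopifnot(is.logical(b), is.matrix(b))
  !b
}

# ensure the fruit (not the background) is TRUE: the dominant population on
# the image border is background, which must come out FALSE
.normalize_polarity <- function(b) {
  border <- c(b[1, ], b[nrow(b), ], b[, 1], b[, ncol(b)])
  if (mean(border) > 0.5) invert_binary(b) else b
}

#' Morphological cleaning of a binary image
#'
#' Opening followed by closing with a disc structuring element: removes
#' protrusions, isolated specks and gaps smaller than the element.
#'
#' @inheritParams binarize
#' @param b logical matrix.
#' @return Logical matrix.
#' @export
morph_clean <- function(b, cfg = preprocess_config()) {
  stopifnot(is.logical(b), is.matrix(b))
  r <- cfg$structuring_element_radius
  kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  x <- EBImage::closing(EBImage::opening(b * 1, kern), kern)
  matrix(as.vector(x) > 0.5, nrow(b), ncol(b))
}

#' Fill holes and remove small components
#'
#' Fills interior holes of connected components, discards components with
#' area below `min_component_area`, and keeps only the largest remaining
#' component (the scene contains exactly one fruit).
#'
#' @inheritParams morph_clean
#' @return Logical matrix with exactly one connected component.
#' @export
remove_noise_fill <- function(b, cfg = preprocess_config()) {
  stopifnot(is.logical(b), is.matrix(b))
  min_area <- cfg$min_component_area
  if (is.null(min_area)) min_area <- 0.001 * length(b)
  filled <- EBImage::fillHull(matrix(as.integer(b), nrow(b), ncol(b)))
  lab <- EBImage::bwlabel(filled)
  areas <- tabulate(as.vector(lab))
  areas[areas < min_area] <- 0L
  if (length(areas) == 0L || max(areas) == 0L)
    stop("no foreground found")
  keep <- which.max(areas)
  matrix(as.vector(lab) == keep, nrow(b), ncol(b))
}

#' Remove the background of an image given a foreground mask
#'
#' Background pixels are set to zero; downstream statistics use the mask to
#' restrict themselves to fruit pixels.
#'
#' @param img H x W x 3 array in `[0,1]`.
#' @param mask logical H x W foreground mask.
#' @return Object of class `masked_image`: list with `image` (background
#'   zeroed) and `mask`.
#' @export
apply_mask <- function(img, mask) {
  .check_rgb(img)
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!identical(dim(img)[1:2], dim(mask)))
    stop("image and mask shapes differ")
  if (!any(mask)) stop("no foreground found")
  out <- img
  for (k in 1:3) {
    plane <- out[, , k]
    plane[!mask] <- 0
    out[, , k] <- plane
  }
  structure(list(image = out, mask = mask), class = "masked_image")
}

#' @export
print.masked_image <- function(x, ...) {
  cat("masked_image:", paste(dim(x$mask), collapse = " x "),
      "px,", sum(x$mask), "fruit pixels\n")
  invisible(x)
}

#' Full segmentation pipeline
#'
#' Composes the five pre-processing steps: gray-level binarization,
#' polarity normalization (inversion, so the fruit is `TRUE`), opening and
#' closing, hole-filling with small-component removal, and background
#' removal. Deterministic.
#'
#' @inheritParams binarize
#' @return List with `masked` (a `masked_image`) and `mask` (logical
#'   matrix).
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  b <- binarize(img, cfg)
  b <- .normalize_polarity(b)
  b <- morph_clean(b, cfg)
  mask <- remove_noise_fill(b, cfg)
  list(masked = apply_mask(img, mask), mask = mask)
}

#' Jaccard index of two binary masks
#'
#' @param a,b logical matrices of equal shape.
#' @return Intersection over union; 1 when both masks are empty.
#' @export
jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
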