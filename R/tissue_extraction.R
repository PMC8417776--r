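#' Convert an RGB slide to 8-bit luminance
#'
#' Rec. 601 luma: `round(0.299 R + 0.587 G + 0.114 B)`, clipped to 0--255.
#'
#' @param image `H x W x 3` array, values 0--255.
#' @return Integer matrix of intensities 0--255.
#' @export
to_intensity <- function(image) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(as.integer(pmin(pmax(round(y), 0), 255)), dim(image)[1], dim(image)[2])
}

#' Intensity histogram of an 8-bit raster
#'
#' @param intensity integer matrix/vector of values 0--255.
#' @return Integer vector of 256 counts, indexed by intensity 0--255.
#' @export
intensity_histogram <- function(intensity) {
  tabulate(as.integer(intensity) + 1L, nbins = 256L)
}

#' Otsu threshold of a 256-bin intensity histogram
#'
#' Returns the threshold `t` maximizing the between-class variance
#' `sigma_b^2(t) = w0(t) w1(t) (mu0(t) - mu1(t))^2`, where class 0 holds
#' intensities `<= t`. Ties are broken by the smallest maximizing `t`. A
#' histogram whose mass sits in a single bin admits no separating threshold
#' and is flagged degenerate (threshold `NA`).
#'
#' @param counts 256 nonnegative counts (total > 0).
#' @return List with `threshold` (integer 0--255 or `NA`), `degenerate`
#'   (logical) and `between_var` (the maximized variance).
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  p <- counts / n
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[256L]
  w1 <- 1 - w0
  sb <- (muT * w0 - mu)^2 / (w0 * w1)
  sb[w0 <= 0 | w1 <= 0] <- 0
  best <- max(sb)
  if (best <= 0)
    return(list(threshold = NA_integer_, degenerate = TRUE, between_var = 0))
  t <- which.max(sb) - 1L   # first (smallest) maximizer
  list(threshold = t, degenerate = FALSE, between_var = best)
}

#' Morphological cleanup parameters for tissue extraction
#'
#' @param opening_radius_px,closing_radius_px disc radii for binary opening
#'   (kills speckle) and closing (bridges sinusoids); 0 skips the step.
#' @param min_object_area_px connected components smaller than this are
#'   removed.
#' @param fill_holes fill enclosed holes in the mask.
#' @return A named list of class `morphology_params`.
#' @export
morphology_params <- function(opening_radius_px = 2L, closing_radius_px = 4L,
                              min_object_area_px = 256L, fill_holes = TRUE) {
  stopifnot(opening_radius_px >= 0L, closing_radius_px >= 0L,
            min_object_area_px >= 0L)
  structure(list(opening_radius_px = as.integer(opening_radius_px),
                 closing_radius_px = as.integer(closing_radius_px),
                 min_object_area_px = as.integer(min_object_area_px),
                 fill_holes = isTRUE(fill_holes)),
            class = "morphology_params")
}

disc_op <- function(mask, radius, op) {
  if (radius < 1L) return(mask)
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  out <- op(matrix(as.numeric(mask), nrow(mask), ncol(mask)), brush)
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

#' Extract the tissue region of a slide
#'
#' Otsu-thresholds the luminance image (tissue is the dark side: histology
#' backgrounds are near-white), then cleans the binary mask by disc opening,
#' disc closing, removal of small connected components, and optional hole
#' filling. A degenerate Otsu result (single-intensity image) yields an
#' empty mask.
#'
#' @param image `H x W x 3` slide raster, values 0--255.
#' @param morph a [morphology_params()] object.
#' @return An object of class `tissue_mask`: list with `mask` (logical
#'   matrix), `area_px` (A_tissue, the true-pixel count), `threshold` and
#'   `degenerate`.
#' @export
extract_tissue <- function(image, morph = morphology_params()) {
  inten <- to_intensity(image)
  if (max(morph$opening_radius_px, morph$closing_radius_px) > min(dim(inten)) / 4)
    stop("morphology radii must be <= min(image dims)/4")
  ot <- otsu_threshold(intensity_histogram(inten))
  if (ot$degenerate) {
    mask <- matrix(FALSE, nrow(inten), ncol(inten))
    return(structure(list(mask = mask, area_px = 0L, threshold = NA_integer_,
                          degenerate = TRUE), class = "tissue_mask"))
  }
  mask <- inten <= ot$threshold
  mask <- disc_op(mask, morph$opening_radius_px, EBImage::opening)
  mask <- disc_op(mask, morph$closing_radius_px, EBImage::closing)
  if (morph$min_object_area_px > 0L && any(mask)) {
    lab <- label_components(mask, 8L)
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= morph$min_object_area_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (morph$fill_holes && any(mask)) {
    fh <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
    mask <- matrix(as.numeric(fh) > 0.5, nrow(mask), ncol(mask))
  }
  structure(list(mask = mask, area_px = sum(mask), threshold = ot$threshold,
                 degenerate = FALSE), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf("Tissue mask: %d x %d px, A_tissue = %d px (Otsu t = %s)\n",
              nrow(x$mask), ncol(x$mask), x$area_px,
              ifelse(x$degenerate, "degenerate", x$threshold)))
  invisible(x)
}
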