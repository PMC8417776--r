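#' Accumulate patch probabilities into a per-pixel likelihood map
#'
#' Each pixel's likelihood is the mean of the probabilities of the patches
#' covering it (coverage-averaging). Averaging is the normalisation: it keeps
#' every pixel in `[0, 1]` by construction, independent of the slide's own
#' extremes. Pixels covered by no patch get likelihood 0 and coverage 0.
#'
#' @param image_dims `c(height, width)`.
#' @param grid a [build_grid()] result.
#' @param probs probabilities aligned with `grid$origins`, each in `[0, 1]`.
#' @param rescale compatibility switch: `"coverage"` (default) is the
#'   averaging above; `"minmax"` additionally rescales the averaged map to
#'   span `[0, 1]` using its own extremes over covered pixels (non-default;
#'   it makes the downstream threshold slide-relative).
#' @return An object of class `likelihood_map`: list with `values` (real
#'   raster in `[0, 1]`), `coverage` (integer raster), `patch_size`,
#'   `stride`.
#' @export
accumulate_map <- function(image_dims, grid, probs,
                           rescale = c("coverage", "minmax")) {
  rescale <- match.arg(rescale)
  if (length(probs) != nrow(grid$origins))
    stop("probs must align with grid$origins")
  if (length(probs) && (min(probs) < 0 || max(probs) > 1))
    stop("probabilities must lie in [0, 1]")
  H <- image_dims[1]; W <- image_dims[2]; P <- grid$patch_size
  pad <- P - 1L
  acc <- matrix(0, H + pad, W + pad)
  cov <- matrix(0, H + pad, W + pad)
  if (length(probs)) {
    at <- grid$origins + P   # origin (r,c) 0-based -> padded index r+P
    lin <- (at[, 2] - 1L) * (H + pad) + at[, 1]
    psum <- rowsum(probs, lin)
    pcnt <- rowsum(rep(1, length(lin)), lin)
    lin_u <- as.integer(rownames(psum))
    acc[lin_u] <- psum
    cov[lin_u] <- pcnt
  }
  value_sum <- window_sums(acc, P)
  coverage <- window_sums(cov, P)
  values <- ifelse(coverage > 0, value_sum / pmax(coverage, 1), 0)
  if (rescale == "minmax" && any(coverage > 0)) {
    v <- values[coverage > 0]
    rng <- range(v)
    if (diff(rng) > 0)
      values[coverage > 0] <- (v - rng[1]) / diff(rng)
  }
  structure(list(values = values, coverage = matrix(as.integer(round(coverage)), H, W),
                 patch_size = P, stride = grid$stride),
            class = "likelihood_map")
}

#' Threshold a likelihood map into a lesion mask
#'
#' The lesion mask is `values >= theta`, intersected with the tissue mask and
#' with the covered region, so A_lesion can never exceed A_tissue. The
#' default cut of 0.9 discards low-likelihood areas.
#'
#' @param map a [accumulate_map()] result.
#' @param tissue a [extract_tissue()] result (or list with logical `mask`).
#' @param theta threshold in `[0, 1]`; the comparison is inclusive (`>=`).
#' @return An object of class `lesion_mask`: list with `mask`, `area_px`
#'   (A_lesion) and `theta`.
#' @export
threshold_map <- function(map, tissue, theta = 0.9) {
  stopifnot(theta >= 0, theta <= 1)
  if (!identical(dim(map$values), dim(tissue$mask)))
    stop("likelihood map and tissue mask dimensions differ")
  mask <- (map$values >= theta) & tissue$mask & (map$coverage > 0L)
  structure(list(mask = mask, area_px = sum(mask), theta = theta),
            class = "lesion_mask")
}

#' Count lesion components
#'
#' Number of connected components of a binary mask with area at least
#' `min_area_px`, under 8- (default) or 4-connectivity. This is the
#' automated analogue of counting discrete lesions on a slide.
#'
#' @param mask logical matrix (or a `lesion_mask` object).
#' @param connectivity 4 or 8.
#' @param min_area_px minimum component area in pixels.
#' @return Nonnegative integer count.
#' @export
count_components <- function(mask, connectivity = 8L, min_area_px = 0L) {
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  lab <- label_components(mask, as.integer(connectivity))
  if (max(lab) == 0L) return(0L)
  areas <- tabulate(lab[lab > 0L])
  sum(areas >= min_area_px)
}

#' Lesion burden of one slide
#'
#' Combines the tissue and lesion masks into the per-slide quantification:
#' areas, their ratio `A_lesion / A_tissue`, and the filtered lesion
#' component count. A slide without tissue has an undefined ratio, reported
#' as `NA` (never 0/0) and flagged.
#'
#' @param tissue a [extract_tissue()] result.
#' @param lesion a [threshold_map()] result (`lesion$mask` must be a subset
#'   of `tissue$mask`).
#' @param slide_id identifier carried into the result.
#' @param connectivity,min_component_area_px passed to [count_components()];
#'   the default 64 px floor suppresses speckle-sized detections.
#' @return An object of class `quant_result`: list with `slide_id`,
#'   `A_tissue_px`, `A_lesion_px`, `ratio`, `n_lesion_components`, `theta`,
#'   `no_tissue`.
#' @export
quantify <- function(tissue, lesion, slide_id = NA_character_,
                     connectivity = 8L, min_component_area_px = 64L) {
  if (any(lesion$mask & !tissue$mask))
    stop("lesion mask must be a subset of the tissue mask")
  at <- tissue$area_px
  al <- lesion$area_px
  no_tissue <- at == 0L
  structure(list(slide_id = slide_id,
                 A_tissue_px = at, A_lesion_px = al,
                 ratio = if (no_tissue) NA_real_ else al / at,
                 n_lesion_components = count_components(lesion$mask, connectivity,
                                                        min_component_area_px),
                 theta = lesion$theta, no_tissue = no_tissue),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  if (x$no_tissue) {
    cat(sprintf("Slide %s: no tissue detected (ratio undefined)\n", x$slide_id))
  } else {
    cat(sprintf("Slide %s: A_tissue = %d px, A_lesion = %d px, ratio = %.4f (theta = %g), %d lesion component(s)\n",
                x$slide_id, x$A_tissue_px, x$A_lesion_px, x$ratio, x$theta,
                x$n_lesion_components))
  }
  invisible(x)
}

#' @export
as.data.frame.quant_result <- function(x, ...) {
  data.frame(slide_id = x$slide_id, A_tissue_px = x$A_tissue_px,
             A_lesion_px = x$A_lesion_px, ratio = x$ratio,
             n_components = x$n_lesion_components, theta = x$theta,
             no_tissue = x$no_tissue, stringsAsFactors = FALSE)
}

#' Write a likelihood map as a 16-bit grayscale TIFF
#'
#' Pixel value `round(65535 * likelihood)`, preserving the map's continuous
#' scale far beyond 8-bit display precision.
#'
#' @param map a [accumulate_map()] result.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_likelihood_map <- function(map, path) {
  tiff::writeTIFF(map$values, path, bits.per.sample = 16L)
  invisible(path)
}
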