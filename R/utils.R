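# Summed-area table with a zero-padded leading row/column, so window sums
# reduce to four lookups.
integral_image <- function(m) {
  ii <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  ii[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  ii
}

# Sums over every ph x pw window fully inside `m`; returns an
# (nrow - ph + 1) x (ncol - pw + 1) matrix indexed by the window's top-left
# corner (1-based).
window_sums <- function(m, ph, pw = ph) {
  H <- nrow(m); W <- ncol(m)
  if (ph > H || pw > W) stop("window larger than matrix")
  ii <- integral_image(m)
  r <- seq_len(H - ph + 1L); cc <- seq_len(W - pw + 1L)
  ii[r + ph, cc + pw, drop = FALSE] - ii[r, cc + pw, drop = FALSE] -
    ii[r + ph, cc, drop = FALSE] + ii[r, cc, drop = FALSE]
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Small deterministic seed derivation; keeps results in 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 7919) %% 2147483629L)
}

#' Dice overlap between two binary masks
#'
#' Computes `2|A n B| / (|A| + |B|)`, the standard segmentation agreement
#' score. Two empty masks agree perfectly and score 1.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Read and write slide images and binary masks
#'
#' Slides are RGB rasters stored as `H x W x 3` arrays with integer values in
#' 0--255; masks are logical matrices written as 0/255 single-channel PNGs.
#'
#' @param path file path (PNG).
#' @param image `H x W x 3` array, values 0--255.
#' @param mask logical matrix.
#' @return `read_slide` returns an `H x W x 3` array; `read_mask` a logical
#'   matrix. The writers return `path`, invisibly.
#' @export
read_slide <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' @rdname read_slide
#' @export
write_slide <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname read_slide
#' @export
read_mask <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x > 0.5
}

#' @rdname read_slide
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

# Connected-component labelling with selectable connectivity.
#
# 4-connectivity defers to EBImage::bwlabel. 8-connectivity is reduced to the
# 4-connected case on a 2x upsampled raster: each pixel becomes a 2x2 block
# and every diagonally adjacent pair of foreground pixels gets a one-subpixel
# bridge at their shared corner, which connects exactly the pairs that
# 8-connectivity would connect.
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) return(matrix(0L, H, W))
  if (connectivity == 4L) {
    lab <- EBImage::bwlabel(matrix(as.numeric(mask), H, W))
    return(matrix(as.integer(lab), H, W))
  }
  up <- kronecker(mask + 0, matrix(1, 2L, 2L)) > 0
  if (H > 1L && W > 1L) {
    d1 <- mask[-H, -W, drop = FALSE] & mask[-1L, -1L, drop = FALSE]  # (i,j) with (i+1,j+1)
    if (any(d1)) {
      idx <- which(d1, arr.ind = TRUE)
      up[cbind(2L * idx[, 1L], 2L * idx[, 2L] + 1L)] <- TRUE
    }
    d2 <- mask[-1L, -W, drop = FALSE] & mask[-H, -1L, drop = FALSE]  # (i+1,j) with (i,j+1)
    if (any(d2)) {
      idx <- which(d2, arr.ind = TRUE)
      up[cbind(2L * idx[, 1L], 2L * idx[, 2L])] <- TRUE
    }
  }
  labup <- EBImage::bwlabel(matrix(as.numeric(up), 2L * H, 2L * W))
  lab <- matrix(as.integer(labup), 2L * H, 2L * W)[seq(1L, 2L * H, 2L),
                                                   seq(1L, 2L * W, 2L)]
  lab[!mask] <- 0L
  # relabel consecutively
  keep <- sort(unique(lab[lab > 0L]))
  matrix(match(lab, keep, nomatch = 0L), H, W)
}
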