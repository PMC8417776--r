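# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

small_spec <- function(...) {
  slide_spec(width_px = 192L, height_px = 192L, ...)
}

fixture_slide <- function() {
  if (is.null(fixture_env$slide))
    fixture_env$slide <- generate_slide(small_spec(target_lesion_fraction = 0.2,
                                                   seed = 42L))
  fixture_env$slide
}

fixture_patches <- function() {
  if (is.null(fixture_env$patches)) {
    s <- fixture_slide()
    fixture_env$patches <- sample_patches(s$image, s$ground_truth,
                                          n_per_class = 150L,
                                          purity = 0.9, seed = 7L)
  }
  fixture_env$patches
}

fixture_classifier <- function() {
  if (is.null(fixture_env$clf))
    fixture_env$clf <- patch_classifier(fixture_patches())
  fixture_env$clf
}

# Brute-force Otsu oracle: direct between-class variance at every threshold.
otsu_oracle <- function(counts) {
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  p <- counts / n
  lev <- 0:255
  best <- 0
  bt <- NA_integer_
  for (t in 0:255) {
    w0 <- sum(p[seq_len(t + 1)])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[seq_len(t + 1)] * lev[seq_len(t + 1)]) / w0
    mu1 <- sum(p[(t + 2):256] * lev[(t + 2):256]) / w1
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (!is.finite(sb)) next
    if (sb > best) { best <- sb; bt <- t }
  }
  list(threshold = bt, degenerate = best <= 0, between_var = best)
}

# circular shift of a matrix or H x W x 3 array
roll2d <- function(x, dr, dc) {
  H <- dim(x)[1]; W <- dim(x)[2]
  ri <- ((seq_len(H) - 1 - dr) %% H) + 1
  ci <- ((seq_len(W) - 1 - dc) %% W) + 1
  if (length(dim(x)) == 3L) x[ri, ci, , drop = FALSE] else x[ri, ci, drop = FALSE]
}
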