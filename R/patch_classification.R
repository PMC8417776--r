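#' Build a sliding-window patch grid over the tissue region
#'
#' Candidate origins along each axis are `0, S, 2S, ...` plus the flush
#' position `dim - P` when the stride grid does not already reach it, so the
#' whole raster can be covered. Origins whose patch has tissue fraction below
#' `min_tissue_frac` are dropped.
#'
#' @param image_dims `c(height, width)` in pixels.
#' @param tissue a [extract_tissue()] result (or a list with a logical
#'   `mask`).
#' @param patch_size patch side P in pixels (>= 2, <= min(image dims)).
#' @param stride stride S in pixels (>= 1).
#' @param min_tissue_frac minimum patch tissue fraction in `[0, 1]` for an
#'   origin to be retained.
#' @return An object of class `patch_grid`: list with `patch_size`, `stride`,
#'   `origins` (n x 2 integer matrix of 0-based top-left `(row, col)`
#'   corners, unique and row-major sorted), `tissue_fraction` (per origin)
#'   and `image_dims`.
#' @export
build_grid <- function(image_dims, tissue, patch_size = DEFAULT_PATCH_SIZE,
                       stride = 2L, min_tissue_frac = 0.5) {
  H <- image_dims[1]; W <- image_dims[2]
  P <- as.integer(patch_size); S <- as.integer(stride)
  if (P > min(H, W)) stop("patch_size larger than image")
  stopifnot(P >= 2L, S >= 1L, min_tissue_frac >= 0, min_tissue_frac <= 1)
  axis_pos <- function(d) {
    pos <- seq.int(0L, d - P, by = S)
    if (pos[length(pos)] != d - P) pos <- c(pos, d - P)
    pos
  }
  rows <- axis_pos(H); cols <- axis_pos(W)
  origins <- cbind(rep(rows, each = length(cols)), rep(cols, length(rows)))
  tf_all <- window_sums(tissue$mask + 0, P) / P^2
  tf <- tf_all[origins + 1L]
  keep <- tf >= min_tissue_frac
  structure(list(patch_size = P, stride = S,
                 origins = origins[keep, , drop = FALSE],
                 tissue_fraction = tf[keep],
                 image_dims = c(H, W)),
            class = "patch_grid")
}

#' Texture features of one RGB patch
#'
#' Per channel: mean, sample SD, horizontal gradient energy and vertical
#' gradient energy (mean absolute difference of column-adjacent and
#' row-adjacent pixels respectively) -- 12 features for RGB, a compact
#' stand-in for learned convolutional features.
#'
#' @param patch `P x P x 3` array.
#' @return Named numeric vector of length 12.
#' @export
extract_features <- function(patch) {
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L || d[1] != d[2] || d[1] < 2L)
    stop("expected a P x P x 3 patch with P >= 2")
  feats <- lapply(1:3, function(ch) {
    m <- patch[, , ch]
    c(mean = mean(m), sd = sd(as.vector(m)),
      grad_h = mean(abs(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE])),
      grad_v = mean(abs(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])))
  })
  out <- unlist(feats)
  names(out) <- paste(rep(c("r", "g", "b"), each = 4L),
                      rep(c("mean", "sd", "grad_h", "grad_v"), 3L), sep = "_")
  out
}

# Integral-image fast path: the same 12 features for many origins at once.
# Exactly equivalent to applying extract_features() patch by patch.
features_for_origins <- function(image, origins, P) {
  n <- nrow(origins)
  out <- matrix(0, n, 12L)
  if (n == 0L) return(out)
  idx <- origins + 1L
  npx <- P * P
  for (ch in 1:3) {
    m <- image[, , ch]
    s1 <- window_sums(m, P)[idx]
    s2 <- window_sums(m * m, P)[idx]
    mu <- s1 / npx
    va <- pmax(s2 - s1^2 / npx, 0) / (npx - 1)
    dh <- abs(m[, -1L, drop = FALSE] - m[, -ncol(m), drop = FALSE])
    dv <- abs(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])
    gh <- window_sums(dh, P, P - 1L)[idx] / (P * (P - 1L))
    gv <- window_sums(dv, P - 1L, P)[idx] / (P * (P - 1L))
    out[, (ch - 1L) * 4L + 1:4] <- cbind(mu, sqrt(va), gh, gv)
  }
  colnames(out) <- paste(rep(c("r", "g", "b"), each = 4L),
                         rep(c("mean", "sd", "grad_h", "grad_v"), 3L), sep = "_")
  out
}

features_of_patchset <- function(train) {
  t(vapply(train$patches, extract_features, numeric(12L)))
}

#' Fit the reference patch classifier
#'
#' An L2-regularised linear logistic model on the 12 texture features of
#' [extract_features()], standing in for the patch-wise CNN of a full
#' deployment (any object honouring the fit/predict-probability contract can
#' be substituted). Features are standardised with training means and SDs;
#' the penalised likelihood is maximised by full-batch Newton iterations to
#' a fixed tolerance, so fitting is deterministic given the data.
#'
#' @param train a `labeled_patches` object from [sample_patches()], or a list
#'   with `features` (n x 12 matrix) and `labels` (0/1).
#' @param reg_strength L2 penalty on the non-intercept weights (default
#'   0.01).
#' @param seed kept for interface symmetry; the fit itself is deterministic
#'   and draws no random numbers.
#' @param tol convergence tolerance on the max absolute coefficient update.
#' @param max_iter Newton iteration cap.
#' @return An object of class `patch_classifier` with coefficients,
#'   standardisation constants, patch size and training accuracy. Supports
#'   `print()`, `summary()`, `coef()` and `predict()`.
#' @export
patch_classifier <- function(train, reg_strength = 0.01, seed = 0L,
                             tol = 1e-8, max_iter = 100L) {
  if (inherits(train, "labeled_patches")) {
    X <- features_of_patchset(train)
    P <- train$patch_size
  } else {
    X <- as.matrix(train$features)
    P <- if (!is.null(train$patch_size)) train$patch_size else NA_integer_
  }
  y <- as.numeric(train$labels)
  if (length(unique(y)) < 2L)
    stop("single-class training set: both labels 0 and 1 are required")
  stopifnot(nrow(X) == length(y), reg_strength >= 0)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl <= 0] <- 1
  Z <- cbind(1, sweep(sweep(X, 2L, ctr), 2L, scl, "/"))
  p1 <- ncol(Z)
  pen <- diag(c(0, rep(reg_strength, p1 - 1L)))
  w <- numeric(p1)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(Z %*% w)
    mu <- sigmoid(eta)
    grad <- drop(crossprod(Z, mu - y)) + drop(pen %*% w)
    wts <- pmax(mu * (1 - mu), 1e-10)
    Hm <- crossprod(Z, Z * wts) + pen + diag(1e-10, p1)
    step <- solve(Hm, grad)
    w <- w - step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  prob <- sigmoid(drop(Z %*% w))
  acc <- mean((prob >= 0.5) == (y == 1))
  coefs <- setNames(w, c("(Intercept)", colnames(X)))
  structure(list(coefficients = coefs, center = ctr, scale = scl,
                 patch_size = P, reg_strength = reg_strength,
                 converged = converged, n_iter = it,
                 training_accuracy = acc, n_train = length(y)),
            class = "patch_classifier")
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat(sprintf(paste0("Patch classifier (ridge logistic on 12 texture features)\n",
                     "  patch size: %s px | n_train: %d | reg: %g\n",
                     "  converged in %d Newton steps | training accuracy: %.3f\n"),
              x$patch_size, x$n_train, x$reg_strength, x$n_iter,
              x$training_accuracy))
  invisible(x)
}

#' @export
coef.patch_classifier <- function(object, ...) object$coefficients

#' @export
summary.patch_classifier <- function(object, ...) {
  print(object)
  cat("Standardised coefficients:\n")
  print(round(object$coefficients, 4))
  invisible(object)
}

#' Predict lesion probabilities
#'
#' @param object a fitted [patch_classifier()].
#' @param newdata a feature matrix (n x 12), a `labeled_patches` object, or a
#'   list of `P x P x 3` patches.
#' @param ... unused.
#' @return Numeric vector of lesion probabilities in `[0, 1]`.
#' @export
predict.patch_classifier <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
  else if (inherits(newdata, "labeled_patches")) features_of_patchset(newdata)
  else t(vapply(newdata, extract_features, numeric(12L)))
  if (ncol(X) != length(object$center)) stop("feature dimension mismatch")
  Z <- cbind(1, sweep(sweep(X, 2L, object$center), 2L, object$scale, "/"))
  drop(sigmoid(Z %*% object$coefficients))
}

#' Lesion probability for every patch of a grid
#'
#' Extracts the 12 texture features of every retained grid origin (via an
#' integral-image fast path identical to per-patch extraction) and applies
#' the classifier.
#'
#' @param grid a [build_grid()] result.
#' @param image the slide raster the grid was built on.
#' @param clf a fitted [patch_classifier()].
#' @return Numeric vector of probabilities aligned with `grid$origins`
#'   (length 0 for an empty grid).
#' @export
predict_probs <- function(grid, image, clf) {
  if (!inherits(clf, "patch_classifier") || is.null(clf$coefficients))
    stop("classifier is not fitted")
  if (nrow(grid$origins) == 0L) return(numeric(0))
  X <- features_for_origins(image, grid$origins, grid$patch_size)
  predict(clf, X)
}

#' Serialise a patch classifier to portable JSON
#'
#' @param clf a fitted [patch_classifier()].
#' @param path output JSON path.
#' @return `path` (writer) or the restored `patch_classifier` (reader).
#' @export
write_classifier <- function(clf, path) {
  obj <- unclass(clf)
  # named vectors as JSON objects, so names survive the round-trip
  for (fld in c("coefficients", "center", "scale"))
    obj[[fld]] <- as.list(obj[[fld]])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$coefficients <- unlist(obj$coefficients)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  class(obj) <- "patch_classifier"
  obj
}
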