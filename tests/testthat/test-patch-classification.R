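all_tissue <- function(d) list(mask = matrix(TRUE, d, d))

test_that("the stride grid tiles exactly and honors the flush rule", {
  g <- build_grid(c(100, 100), all_tissue(100), patch_size = 50, stride = 50,
                  min_tissue_frac = 0.5)
  expect_equal(nrow(g$origins), 4L)
  expect_equal(g$origins, cbind(c(0L, 0L, 50L, 50L), c(0L, 50L, 0L, 50L)))

  g2 <- build_grid(c(100, 100), all_tissue(100), patch_size = 40, stride = 30)
  expect_equal(nrow(g2$origins), 9L)           # {0,30,60} per axis, 60 flush
  expect_setequal(unique(g2$origins[, 1]), c(0L, 30L, 60L))

  g3 <- build_grid(c(100, 100), list(mask = matrix(FALSE, 100, 100)), 40, 30)
  expect_equal(nrow(g3$origins), 0L)
  expect_error(build_grid(c(30, 30), all_tissue(30), patch_size = 40, stride = 10),
               "larger")
})

test_that("with no tissue filter and stride <= patch size the grid covers every pixel", {
  g <- build_grid(c(37, 53), list(mask = matrix(TRUE, 37, 53)), patch_size = 8,
                  stride = 5, min_tissue_frac = 0)
  expect_true(all(g$origins[, 1] + 8 <= 37) && all(g$origins[, 2] + 8 <= 53))
  m <- accumulate_map(c(37, 53), g, rep(1, nrow(g$origins)))
  expect_true(all(m$coverage > 0L))
})

test_that("patch features match their definitions", {
  const <- array(37, c(4, 4, 3))
  f <- extract_features(const)
  expect_length(f, 12L)
  expect_true(all(f[grep("sd|grad", names(f))] == 0))
  expect_true(all(f[grep("mean", names(f))] == 37))

  checker <- array(0, c(4, 4, 3))
  checker[, , 1] <- (outer(1:4, 1:4, "+") %% 2) * 255
  f2 <- extract_features(checker)
  expect_equal(unname(f2["r_mean"]), 127.5)
  expect_equal(unname(f2["r_grad_h"]), 255)
  expect_equal(unname(f2["r_grad_v"]), 255)
  expect_error(extract_features(array(0, c(4, 5, 3))), "P x P")
})

test_that("the integral-image fast path equals per-patch feature extraction", {
  set.seed(5)
  img <- array(runif(40 * 40 * 3, 0, 255), c(40, 40, 3))
  P <- 6L
  origins <- cbind(sample(0:(40 - P), 25, replace = TRUE),
                   sample(0:(40 - P), 25, replace = TRUE))
  fast <- lesionquant:::features_for_origins(img, origins, P)
  slow <- t(apply(origins, 1, function(o)
    extract_features(img[(o[1] + 1):(o[1] + P), (o[2] + 1):(o[2] + P), ,
                         drop = FALSE])))
  expect_equal(unname(fast), unname(slow), tolerance = 1e-10)
})

test_that("fitting is deterministic and separable textures are learned", {
  clf <- fixture_classifier()
  expect_gte(clf$training_accuracy, 0.99)
  expect_true(clf$converged)
  clf2 <- patch_classifier(fixture_patches())
  expect_identical(coef(clf), coef(clf2))
})

test_that("single-class training sets are rejected", {
  ps <- fixture_patches()
  bad <- ps
  bad$labels <- rep(0L, length(ps$labels))
  expect_error(patch_classifier(bad), "single-class")
})

test_that("the fit maximizes the penalized likelihood (optim cross-check)", {
  set.seed(20)
  n <- 80L
  X <- cbind(rnorm(n), rnorm(n), rnorm(n))
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.8) > 0)
  reg <- 0.5
  clf <- patch_classifier(list(features = X, labels = y), reg_strength = reg)
  # independent route: BFGS on the same objective with the same standardization
  Z <- cbind(1, scale(X))
  obj <- function(w) {
    eta <- drop(Z %*% w)
    sum(log1p(exp(eta))) - sum(y * eta) + 0.5 * reg * sum(w[-1]^2)
  }
  ref <- optim(numeric(4), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(coef(clf)), unname(ref$par), tolerance = 1e-4)
})

test_that("predictions are probabilities, pure functions of patch content", {
  s <- fixture_slide()
  clf <- fixture_classifier()
  ts <- extract_tissue(s$image)
  g <- build_grid(dim(ts$mask), ts, 3, 2)
  p <- predict_probs(g, s$image, clf)
  expect_length(p, nrow(g$origins))
  expect_true(all(p >= 0 & p <= 1))
  # ordering invariance: permuting origins permutes probabilities
  perm <- sample(nrow(g$origins))
  g2 <- g; g2$origins <- g$origins[perm, , drop = FALSE]
  expect_equal(predict_probs(g2, s$image, clf), p[perm])
  # empty grid
  g0 <- g; g0$origins <- g$origins[0, , drop = FALSE]
  expect_length(predict_probs(g0, s$image, clf), 0L)
  expect_error(predict_probs(g, s$image, structure(list(), class = "patch_classifier")),
               "not fitted")
})

test_that("a pure-lesion prototype patch scores a high lesion probability", {
  ps <- fixture_patches()
  clf <- fixture_classifier()
  proto <- ps$patches[[which(ps$labels == 1L)[1]]]
  expect_gt(predict(clf, list(proto)), 0.9)
})

test_that("standardization absorbs a common affine rescaling of all patches", {
  ps <- fixture_patches()
  ps2 <- ps
  ps2$patches <- lapply(ps$patches, function(p) 0.5 * p + 20)
  clf1 <- patch_classifier(ps)
  clf2 <- patch_classifier(ps2)
  test_idx <- c(3L, 77L, 200L)
  p1 <- predict(clf1, ps$patches[test_idx])
  p2 <- predict(clf2, ps2$patches[test_idx])
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("classifier serialization round-trips through JSON", {
  clf <- fixture_classifier()
  f <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, f)
  back <- read_classifier(f)
  expect_equal(coef(back), coef(clf))
  ps <- fixture_patches()
  expect_equal(predict(back, ps$patches[1:5]), predict(clf, ps$patches[1:5]),
               tolerance = 1e-12)
})
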