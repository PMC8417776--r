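fake_grid <- function(P, origins, dims) {
  structure(list(patch_size = P, stride = P, origins = origins,
                 tissue_fraction = rep(1, nrow(origins)), image_dims = dims),
            class = "patch_grid")
}

test_that("a single patch writes its probability over exactly its footprint", {
  g <- fake_grid(5L, cbind(2L, 3L), c(20, 20))
  m <- accumulate_map(c(20, 20), g, 0.7)
  inside <- matrix(FALSE, 20, 20); inside[3:7, 4:8] <- TRUE
  expect_true(all(m$values[inside] == 0.7))
  expect_true(all(m$values[!inside] == 0))
  expect_true(all(m$coverage[inside] == 1L))
  expect_true(all(m$coverage[!inside] == 0L))
})

test_that("coverage-averaging normalizes overlapping probabilities", {
  g <- fake_grid(5L, rbind(c(2L, 3L), c(2L, 3L)), c(20, 20))
  m <- accumulate_map(c(20, 20), g, c(1, 0))
  expect_equal(m$values[5, 5], 0.5)
  expect_equal(m$coverage[5, 5], 2L)
  # partial overlap averages only where both cover
  g2 <- fake_grid(4L, rbind(c(0L, 0L), c(2L, 2L)), c(10, 10))
  m2 <- accumulate_map(c(10, 10), g2, c(1, 0))
  expect_equal(m2$values[3, 3], 0.5)   # overlap of both patches
  expect_equal(m2$values[1, 1], 1)     # only the first
  expect_equal(m2$values[6, 6], 0)     # only the second
})

test_that("map values stay in [0, 1] for arbitrary probability inputs", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    org <- cbind(sample(0:26, n, replace = TRUE), sample(0:26, n, replace = TRUE))
    m <- accumulate_map(c(30, 30), fake_grid(4L, org, c(30, 30)), runif(n))
    expect_true(all(m$values >= 0 & m$values <= 1))
    expect_true(all(m$values[m$coverage == 0L] == 0))
  }
  expect_error(accumulate_map(c(30, 30), fake_grid(4L, cbind(0L, 0L), c(30, 30)),
                              c(0.5, 0.5)), "align")
})

test_that("thresholding is inclusive, masked to covered tissue, and monotone", {
  g <- fake_grid(5L, rbind(c(0L, 0L), c(10L, 10L)), c(20, 20))
  m <- accumulate_map(c(20, 20), g, c(0.89, 0.95))
  tis <- list(mask = matrix(TRUE, 20, 20))
  expect_equal(threshold_map(m, tis, 0.9)$area_px, 25L)   # only the 0.95 patch
  expect_equal(threshold_map(m, tis, 0.96)$area_px, 0L)
  # theta = 0 keeps exactly the covered tissue pixels
  expect_equal(threshold_map(m, tis, 0)$area_px, 50L)
  # A_lesion(theta) nonincreasing over a theta grid
  s <- fixture_slide()
  res <- quantify_slide(s$image, fixture_classifier(), keep_rasters = TRUE)
  areas <- vapply(seq(0, 1, by = 0.1), function(th)
    threshold_map(res$map, res$tissue, th)$area_px, 1L)
  expect_true(all(diff(areas) <= 0))
  expect_true(all(areas <= res$tissue$area_px))
})

test_that("lesion burden arithmetic and degenerate cases", {
  tis <- structure(list(mask = matrix(TRUE, 10, 10), area_px = 100L),
                   class = "tissue_mask")
  les0 <- structure(list(mask = matrix(FALSE, 10, 10), area_px = 0L, theta = 0.9),
                    class = "lesion_mask")
  expect_equal(quantify(tis, les0)$ratio, 0)
  lesA <- structure(list(mask = matrix(TRUE, 10, 10), area_px = 100L, theta = 0.9),
                    class = "lesion_mask")
  expect_equal(quantify(tis, lesA)$ratio, 1)
  none <- structure(list(mask = matrix(FALSE, 10, 10), area_px = 0L),
                    class = "tissue_mask")
  q <- quantify(none, les0)
  expect_true(q$no_tissue)
  expect_true(is.na(q$ratio))
  bad <- structure(list(mask = matrix(TRUE, 10, 10), area_px = 100L, theta = 0.9),
                   class = "lesion_mask")
  expect_error(quantify(none, bad), "subset")
})

test_that("component counting honors connectivity and the area floor", {
  expect_equal(count_components(matrix(FALSE, 5, 5)), 0L)
  two <- matrix(FALSE, 30, 30)
  d <- outer(1:30, 1:30, function(a, b) sqrt((a - 8)^2 + (b - 8)^2))
  two[d <= 4] <- TRUE
  d2 <- outer(1:30, 1:30, function(a, b) sqrt((a - 22)^2 + (b - 22)^2))
  two[d2 <= 4] <- TRUE
  expect_equal(count_components(two), 2L)
  diagm <- matrix(FALSE, 2, 2); diagm[1, 1] <- TRUE; diagm[2, 2] <- TRUE
  expect_equal(count_components(diagm, connectivity = 8), 1L)
  expect_equal(count_components(diagm, connectivity = 4), 2L)
  expect_equal(count_components(two, min_area_px = 1000L), 0L)
})

test_that("4-connected labelling agrees with the EBImage oracle on random masks", {
  set.seed(12)
  for (i in 1:10) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    mine <- count_components(m, connectivity = 4)
    oracle <- max(EBImage::bwlabel(matrix(as.numeric(m), 20, 20)))
    expect_equal(mine, as.integer(oracle))
  }
})

test_that("8-connected labelling matches a flood-fill oracle on random masks", {
  flood_count <- function(m) {
    lab <- matrix(0L, nrow(m), ncol(m)); nl <- 0L
    for (start in which(m & lab == 0L)) {
      if (lab[start] > 0L) next
      nl <- nl + 1L; queue <- start
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        if (lab[cur] > 0L) next
        lab[cur] <- nl
        r <- (cur - 1L) %% nrow(m) + 1L; cc <- (cur - 1L) %/% nrow(m) + 1L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; c2 <- cc + dc
          if (rr >= 1 && rr <= nrow(m) && c2 >= 1 && c2 <= ncol(m) &&
              m[rr, c2] && lab[rr, c2] == 0L)
            queue <- c(queue, (c2 - 1L) * nrow(m) + rr)
        }
      }
    }
    nl
  }
  set.seed(13)
  for (i in 1:6) {
    m <- matrix(runif(225) < 0.3, 15, 15)
    expect_equal(count_components(m, connectivity = 8), flood_count(m))
  }
})

test_that("the pipeline recovers a planted 20% lesion burden end-to-end", {
  s <- generate_slide(slide_spec(target_lesion_fraction = 0.2, seed = 31))
  clf <- fixture_classifier()
  q <- quantify_slide(s$image, clf, "e2e")
  expect_gte(q$ratio, 0.17)
  expect_lte(q$ratio, 0.23)
  expect_gte(q$n_lesion_components, 1L)
})

test_that("translating content by a stride multiple barely moves the ratio", {
  s <- fixture_slide()
  clf <- fixture_classifier()
  r1 <- quantify_slide(s$image, clf)$ratio
  r2 <- quantify_slide(roll2d(s$image, 4, 8), clf)$ratio
  expect_lte(abs(r1 - r2), 0.005)
})

test_that("likelihood maps round-trip through 16-bit TIFF", {
  s <- fixture_slide()
  res <- quantify_slide(s$image, fixture_classifier(), keep_rasters = TRUE)
  f <- withr::local_tempfile(fileext = ".tif")
  write_likelihood_map(res$map, f)
  back <- tiff::readTIFF(f)
  expect_lte(max(abs(back - res$map$values)), 1 / 65535)
})
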