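#' Specification of a synthetic H&E-like slide
#'
#' Collects the parameters of the synthetic slide generator: raster size,
#' background brightness, tissue and lesion colours, speckle noise, nucleus
#' density, and the planted lesion fraction with its tolerance. The defaults
#' emulate an eosin-pink parenchyma on a bright scanner background with
#' bluish, texture-rich lesion blobs (the appearance of proliferative
#' bile-duct lesions on H&E), at a moderate 512 px working resolution.
#'
#' @param width_px,height_px raster dimensions in pixels (at least four times
#'   the default patch size of 3 px).
#' @param background_intensity background grey level, 0--255 (near-white).
#' @param tissue_color,lesion_color RGB triples, 0--255.
#' @param noise_sd per-channel Gaussian speckle SD in grey levels.
#' @param nucleus_density dark nuclear dots per 1000 px^2 of tissue.
#' @param target_lesion_fraction planted lesion area as a fraction of tissue
#'   area, in `[0, 1)`.
#' @param n_lesion_blobs number of lesion blobs to plant.
#' @param fraction_tolerance admissible absolute deviation of the planted
#'   fraction from its target.
#' @param texture_amp amplitude (grey levels) of the high-frequency uniform
#'   texture added inside lesions.
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec (including this seed).
#' @return An object of class `slide_spec` (a named list).
#' @seealso [generate_slide()]
#' @export
slide_spec <- function(width_px = 512L, height_px = 512L,
                       background_intensity = 245L,
                       tissue_color = c(225, 150, 180),
                       lesion_color = c(150, 130, 205),
                       noise_sd = 8, nucleus_density = 0.3,
                       target_lesion_fraction = 0.2, n_lesion_blobs = 2L,
                       fraction_tolerance = 0.02, texture_amp = 25,
                       seed = 1L) {
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               background_intensity = background_intensity,
               tissue_color = tissue_color, lesion_color = lesion_color,
               noise_sd = noise_sd, nucleus_density = nucleus_density,
               target_lesion_fraction = target_lesion_fraction,
               n_lesion_blobs = as.integer(n_lesion_blobs),
               fraction_tolerance = fraction_tolerance,
               texture_amp = texture_amp, seed = as.integer(seed))
  validate_slide_spec(spec)
  class(spec) <- "slide_spec"
  spec
}

DEFAULT_PATCH_SIZE <- 3L

validate_slide_spec <- function(spec) {
  stopifnot(spec$width_px >= 4L * DEFAULT_PATCH_SIZE,
            spec$height_px >= 4L * DEFAULT_PATCH_SIZE,
            spec$background_intensity >= 0, spec$background_intensity <= 255,
            length(spec$tissue_color) == 3L, length(spec$lesion_color) == 3L,
            spec$noise_sd >= 0, spec$nucleus_density >= 0,
            spec$target_lesion_fraction >= 0, spec$target_lesion_fraction < 1,
            spec$n_lesion_blobs >= 0L, spec$fraction_tolerance > 0)
  if (spec$target_lesion_fraction + spec$fraction_tolerance >= 1)
    stop("target_lesion_fraction + fraction_tolerance must be < 1")
  invisible(spec)
}

# One smooth tissue blob: an ellipse-like region whose radius is modulated by
# a few low-order harmonics, so the outline is irregular but smooth.
tissue_blob_mask <- function(H, W) {
  cy <- H / 2 + runif(1, -0.02, 0.02) * H
  cx <- W / 2 + runif(1, -0.02, 0.02) * W
  r0 <- 0.40 * min(H, W)
  amp <- runif(4, -0.06, 0.06)
  phi <- runif(4, 0, 2 * pi)
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(seq_len(W) - cx, H, W, byrow = TRUE)
  th <- atan2(dy, dx)
  rad <- r0 * (1 + amp[1] * cos(2 * th + phi[1]) + amp[2] * cos(3 * th + phi[2]) +
                 amp[3] * cos(4 * th + phi[3]) + amp[4] * cos(5 * th + phi[4]))
  sqrt(dy^2 + dx^2) <= rad
}

# Grow one connected lesion blob inside `tissue` to ~quota pixels by stamping
# small discs along a random walk whose positions keep the stamp fully inside
# the tissue. Returns the updated lesion mask or NULL when the walk stalls.
grow_lesion_blob <- function(lesion, tissue, interior_ok, quota, stamp_radius = 4L) {
  H <- nrow(tissue); W <- ncol(tissue)
  free <- interior_ok & !lesion
  starts <- which(free)
  if (!length(starts)) return(NULL)
  pos <- arrayInd(starts[sample.int(length(starts), 1L)], c(H, W))
  off <- expand.grid(dr = -stamp_radius:stamp_radius, dc = -stamp_radius:stamp_radius)
  off <- off[off$dr^2 + off$dc^2 <= stamp_radius^2, ]
  added <- 0L
  max_steps <- 60L * ceiling(quota / nrow(off)) + 500L
  for (step in seq_len(max_steps)) {
    rr <- pos[1] + off$dr; cc <- pos[2] + off$dc
    idx <- cbind(rr, cc)
    hit <- tissue[idx] & !lesion[idx]
    if (any(hit)) {
      lesion[idx[hit, , drop = FALSE]] <- TRUE
      added <- added + sum(hit)
    }
    if (added >= quota) return(lesion)
    # propose steps until one keeps the stamp inside the tissue
    moved <- FALSE
    for (try in 1:20) {
      cand <- pos + sample(-3:3, 2L, replace = TRUE)
      if (cand[1] >= 1L && cand[1] <= H && cand[2] >= 1L && cand[2] <= W &&
          interior_ok[cand[1], cand[2]]) {
        pos <- cand; moved <- TRUE; break
      }
    }
    if (!moved) {
      # teleport to an unlesioned interior position to escape dead ends
      free <- interior_ok & !lesion
      starts <- which(free)
      if (!length(starts)) return(NULL)
      pos <- arrayInd(starts[sample.int(length(starts), 1L)], c(H, W))
    }
  }
  NULL
}

#' Generate a synthetic slide with planted ground truth
#'
#' Renders an RGB histology-like raster (bright background, one smooth darker
#' tissue blob, bluish textured lesion blobs grown strictly inside the
#' tissue) together with its ground-truth tissue and lesion masks. Lesion
#' blobs are grown by stamping small discs along a random walk with area
#' feedback until the planted fraction is within `fraction_tolerance` of the
#' target; if that proves impossible the function fails rather than emitting
#' an off-target slide.
#'
#' @param spec a [slide_spec()].
#' @return A list with components `image` (`H x W x 3` array, 0--255) and
#'   `ground_truth` (list of `tissue_mask`, `lesion_mask` -- logical matrices
#'   with `lesion_mask` a subset of `tissue_mask` -- and `planted_fraction`).
#' @examples
#' s <- generate_slide(slide_spec(width_px = 128, height_px = 128,
#'                                target_lesion_fraction = 0.1, seed = 7))
#' s$ground_truth$planted_fraction
#' @export
generate_slide <- function(spec) {
  validate_slide_spec(spec)
  set.seed(spec$seed)
  H <- spec$height_px; W <- spec$width_px
  tissue <- tissue_blob_mask(H, W)
  tissue_px <- sum(tissue)
  f <- spec$target_lesion_fraction
  lesion <- matrix(FALSE, H, W)

  if (f > 0 && tissue_px > 0) {
    if (spec$n_lesion_blobs < 1L)
      stop("unachievable lesion fraction: target > 0 with n_lesion_blobs = 0")
    target_px <- round(f * tissue_px)
    stamp_radius <- 4L
    k <- 2L * stamp_radius + 1L
    # positions whose full stamp window lies inside the tissue
    full <- window_sums(tissue + 0, k) == k * k
    interior_ok <- matrix(FALSE, H, W)
    interior_ok[seq_len(nrow(full)) + stamp_radius,
                seq_len(ncol(full)) + stamp_radius] <- full
    quotas <- diff(round(seq(0, target_px, length.out = spec$n_lesion_blobs + 1L)))
    done <- FALSE
    for (attempt in 1:5) {
      cand <- matrix(FALSE, H, W)
      ok <- TRUE
      for (q in quotas) {
        if (q <= 0L) next
        res <- grow_lesion_blob(cand, tissue, interior_ok, q, stamp_radius)
        if (is.null(res)) { ok <- FALSE; break }
        cand <- res
      }
      if (ok && abs(sum(cand) / tissue_px - f) <= spec$fraction_tolerance) {
        lesion <- cand; done <- TRUE; break
      }
    }
    if (!done)
      stop(sprintf("unachievable lesion fraction %.3f for this tissue region", f))
  }

  img <- array(0, c(H, W, 3L))
  n_les <- sum(lesion)
  for (ch in 1:3) {
    plane <- matrix(spec$background_intensity, H, W)
    plane[tissue] <- spec$tissue_color[ch]
    if (n_les > 0) {
      plane[lesion] <- spec$lesion_color[ch] +
        runif(n_les, -spec$texture_amp, spec$texture_amp)
    }
    img[, , ch] <- plane
  }
  # nuclei: small dark dots scattered in the tissue
  if (spec$nucleus_density > 0 && tissue_px > 0) {
    n_nuc <- rpois(1L, spec$nucleus_density * tissue_px / 1000)
    if (n_nuc > 0) {
      centers <- arrayInd(sample(which(tissue), min(n_nuc, tissue_px)), c(H, W))
      off <- expand.grid(dr = -1:1, dc = -1:1)
      off <- off[abs(off$dr) + abs(off$dc) <= 1L, ]   # plus-shaped dot
      nuc_col <- c(90, 60, 130)
      for (i in seq_len(nrow(centers))) {
        rr <- centers[i, 1] + off$dr; cc <- centers[i, 2] + off$dc
        keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
        for (ch in 1:3) img[cbind(rr[keep], cc[keep], ch)] <- nuc_col[ch]
      }
    }
  }
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim(img))
  img <- round(pmin(pmax(img, 0), 255))

  list(image = img,
       ground_truth = list(
         tissue_mask = tissue, lesion_mask = lesion,
         planted_fraction = if (tissue_px > 0) sum(lesion) / tissue_px else 0))
}

#' Sample labelled training patches from a slide with ground truth
#'
#' Draws `n_per_class` square patches per class, without replacement of
#' origins. A lesion patch (label 1) must have ground-truth lesion coverage
#' at least `purity`; a normal patch (label 0) must have lesion coverage at
#' most `1 - purity` and tissue coverage at least `purity`.
#'
#' @param image `H x W x 3` slide raster.
#' @param gt ground-truth list as returned by [generate_slide()].
#' @param patch_size patch side length P in pixels (>= 2).
#' @param n_per_class patches to draw per class.
#' @param purity class-purity requirement in `(0.5, 1]`.
#' @param seed integer seed.
#' @return An object of class `labeled_patches`: list of `patches` (each a
#'   `P x P x 3` array), `labels` (0/1 integer vector), `origins` (0-based
#'   top-left corners), `purity` and `patch_size`.
#' @export
sample_patches <- function(image, gt, patch_size = DEFAULT_PATCH_SIZE,
                           n_per_class = 200L, purity = 0.9, seed = 1L) {
  P <- as.integer(patch_size)
  stopifnot(P >= 2L, purity > 0.5, purity <= 1, n_per_class >= 1L)
  set.seed(seed)
  les_cov <- window_sums(gt$lesion_mask + 0, P) / P^2
  tis_cov <- window_sums(gt$tissue_mask + 0, P) / P^2
  elig1 <- which(les_cov >= purity)
  elig0 <- which(les_cov <= 1 - purity & tis_cov >= purity)
  if (length(elig1) < n_per_class)
    stop(sprintf("starved class: lesion (only %d eligible origins, need %d)",
                 length(elig1), n_per_class))
  if (length(elig0) < n_per_class)
    stop(sprintf("starved class: normal (only %d eligible origins, need %d)",
                 length(elig0), n_per_class))
  pick1 <- sample(elig1, n_per_class)
  pick0 <- sample(elig0, n_per_class)
  dims <- dim(les_cov)
  to_origin <- function(lin) arrayInd(lin, dims) - 1L  # 0-based
  origins <- rbind(to_origin(pick0), to_origin(pick1))
  labels <- rep(c(0L, 1L), each = n_per_class)
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    r <- origins[i, 1]; cc <- origins[i, 2]
    image[(r + 1):(r + P), (cc + 1):(cc + P), , drop = FALSE]
  })
  structure(list(patches = patches, labels = labels, origins = origins,
                 purity = purity, patch_size = P),
            class = "labeled_patches")
}

#' Per-animal lesion-fraction laws for cohort simulation
#'
#' `dist_beta(mean, concentration)` is a Beta law on `(0, 1)` parameterised
#' by its mean and concentration (`shape1 + shape2`); `dist_fixed(value)` is
#' a point mass.
#'
#' @param mean,concentration Beta mean in `(0, 1)` and concentration `> 0`.
#' @param value fixed fraction in `[0, 1)`.
#' @return A distribution object with fields `mean` and `sd` and a sampling
#'   closure, used by [generate_cohort()].
#' @export
dist_beta <- function(mean, concentration = 20) {
  stopifnot(mean > 0, mean < 1, concentration > 0)
  a <- mean * concentration; b <- (1 - mean) * concentration
  structure(list(kind = "beta", mean = mean,
                 sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))),
                 draw = function(n) rbeta(n, a, b)),
            class = "fraction_dist")
}

#' @rdname dist_beta
#' @export
dist_fixed <- function(value) {
  stopifnot(value >= 0, value < 1)
  structure(list(kind = "fixed", mean = value, sd = 0,
                 draw = function(n) rep(value, n)),
            class = "fraction_dist")
}

#' Simulate a multi-arm cohort of synthetic slides
#'
#' One slide per animal; each animal's target lesion fraction is drawn
#' i.i.d. from its arm's law, then a slide is generated at that target. The
#' whole cohort is reproducible from `seed`.
#'
#' @param arms list of arms, each a list with `name`, `n` (animals), `frac`
#'   (a [dist_beta()] / [dist_fixed()] object) and optionally `spec`, a base
#'   [slide_spec()] whose target fraction and seed are overridden per animal.
#' @param seed integer master seed.
#' @return List of per-animal records: `arm`, `animal_id`, `target_fraction`,
#'   `image`, `ground_truth`.
#' @export
generate_cohort <- function(arms, seed = 1L) {
  out <- list(); idx <- 0L
  for (ai in seq_along(arms)) {
    arm <- arms[[ai]]
    stopifnot(!is.null(arm$name), arm$n >= 1L,
              inherits(arm$frac, "fraction_dist"))
    base <- if (is.null(arm$spec)) slide_spec() else arm$spec
    set.seed(derive_seed(seed, ai))
    fr <- arm$frac$draw(arm$n)
    fr <- pmin(fr, 1 - base$fraction_tolerance - 1e-9)
    for (j in seq_len(arm$n)) {
      idx <- idx + 1L
      sp <- base
      sp$target_lesion_fraction <- fr[j]
      sp$seed <- derive_seed(seed, 1000L + idx)
      animal_id <- sprintf("%s_%02d", arm$name, j)
      sl <- tryCatch(generate_slide(sp), error = function(e)
        stop(sprintf("animal %s: %s", animal_id, conditionMessage(e)), call. = FALSE))
      out[[idx]] <- list(arm = arm$name, animal_id = animal_id,
                         target_fraction = fr[j], image = sl$image,
                         ground_truth = sl$ground_truth,
                         seed = sp$seed)
    }
  }
  out
}

#' Write a simulated cohort to disk
#'
#' Writes each slide as an RGB PNG, its masks as 0/255 PNGs, and a manifest
#' CSV with columns arm, animal_id, image_path, tissue_mask_path,
#' lesion_mask_path, planted_fraction, seed.
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly; the manifest is written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    ip <- file.path(dir, paste0(rec$animal_id, ".png"))
    tp <- file.path(dir, paste0(rec$animal_id, "_tissue.png"))
    lp <- file.path(dir, paste0(rec$animal_id, "_lesion.png"))
    write_slide(rec$image, ip)
    write_mask(rec$ground_truth$tissue_mask, tp)
    write_mask(rec$ground_truth$lesion_mask, lp)
    data.frame(arm = rec$arm, animal_id = rec$animal_id,
               image_path = ip, tissue_mask_path = tp, lesion_mask_path = lp,
               planted_fraction = rec$ground_truth$planted_fraction,
               seed = rec$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
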