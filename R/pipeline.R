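#' Quantify a single slide end-to-end
#'
#' Tissue extraction, patch grid, patch probabilities, likelihood map,
#' thresholding and lesion-burden computation for one slide.
#'
#' @param image `H x W x 3` slide raster, 0--255.
#' @param clf a fitted [patch_classifier()].
#' @param slide_id identifier carried into the result.
#' @param patch_size,stride,min_tissue_frac grid parameters (see
#'   [build_grid()]).
#' @param theta likelihood threshold (default 0.9).
#' @param morph tissue-extraction [morphology_params()].
#' @param min_component_area_px lesion component area floor.
#' @param keep_rasters also return the likelihood map and masks.
#' @return A [quantify()] result; with `keep_rasters = TRUE`, a list with
#'   `quant`, `tissue`, `map`, `lesion`.
#' @export
quantify_slide <- function(image, clf, slide_id = NA_character_,
                           patch_size = DEFAULT_PATCH_SIZE, stride = 2L,
                           min_tissue_frac = 0.5, theta = 0.9,
                           morph = morphology_params(),
                           min_component_area_px = 64L,
                           keep_rasters = FALSE) {
  tissue <- extract_tissue(image, morph)
  dims <- dim(tissue$mask)
  if (tissue$area_px == 0L) {
    lesion <- structure(list(mask = matrix(FALSE, dims[1], dims[2]),
                             area_px = 0L, theta = theta), class = "lesion_mask")
    q <- quantify(tissue, lesion, slide_id,
                  min_component_area_px = min_component_area_px)
    if (keep_rasters) return(list(quant = q, tissue = tissue, map = NULL,
                                  lesion = lesion))
    return(q)
  }
  grid <- build_grid(dims, tissue, patch_size, stride, min_tissue_frac)
  probs <- predict_probs(grid, image, clf)
  map <- accumulate_map(dims, grid, probs)
  lesion <- threshold_map(map, tissue, theta)
  q <- quantify(tissue, lesion, slide_id,
                min_component_area_px = min_component_area_px)
  if (keep_rasters) return(list(quant = q, tissue = tissue, map = map,
                                lesion = lesion))
  q
}

#' Synthesise a cohort to disk
#'
#' Generates the slides of [generate_cohort()] and writes images, masks and
#' the manifest CSV via [write_cohort()].
#'
#' @param out_dir output directory.
#' @param arms,seed see [generate_cohort()].
#' @return The manifest data frame, invisibly.
#' @export
run_synth <- function(out_dir, arms, seed = 1L) {
  cohort <- generate_cohort(arms, seed)
  write_cohort(cohort, out_dir)
}

load_cohort <- function(x) {
  if (is.character(x)) x <- read.csv(x, stringsAsFactors = FALSE)
  if (is.data.frame(x)) {
    return(lapply(seq_len(nrow(x)), function(i) {
      list(arm = x$arm[i], animal_id = x$animal_id[i],
           image = read_slide(x$image_path[i]),
           ground_truth = list(
             tissue_mask = read_mask(x$tissue_mask_path[i]),
             lesion_mask = read_mask(x$lesion_mask_path[i]),
             planted_fraction = x$planted_fraction[i]))
    }))
  }
  x   # already an in-memory cohort list
}

#' Train the patch classifier on a cohort with ground truth
#'
#' Pools labelled patches across the cohort's slides (lesion patches from
#' slides that carry lesions, normal patches from all slides) until
#' `n_per_class` per class are collected, then fits the reference
#' classifier. Fails with an explicit starved-class error when the cohort
#' cannot supply a class.
#'
#' @param cohort a manifest path, manifest data frame, or in-memory cohort
#'   from [generate_cohort()].
#' @param n_per_class training patches per class.
#' @param patch_size,purity see [sample_patches()].
#' @param reg_strength,seed see [patch_classifier()].
#' @param out_file optional path for the serialized classifier (JSON).
#' @return The fitted `patch_classifier`.
#' @export
run_train <- function(cohort, n_per_class = 200L,
                      patch_size = DEFAULT_PATCH_SIZE, purity = 0.9,
                      reg_strength = 0.01, seed = 1L, out_file = NULL) {
  cohort <- load_cohort(cohort)
  n_slides <- length(cohort)
  stopifnot(n_slides >= 1L)
  P <- as.integer(patch_size)
  # eligible origins per slide and class, then even allocation over the
  # slides that can actually supply each class
  elig <- lapply(cohort, function(rec) {
    gt <- rec$ground_truth
    les_cov <- window_sums(gt$lesion_mask + 0, P) / P^2
    tis_cov <- window_sums(gt$tissue_mask + 0, P) / P^2
    list(`0` = which(les_cov <= 1 - purity & tis_cov >= purity),
         `1` = which(les_cov >= purity),
         dims = dim(les_cov))
  })
  take_patches <- function(lab) {
    avail <- vapply(elig, function(e) length(e[[lab]]), 1L)
    if (sum(avail) < n_per_class)
      stop(sprintf("starved class: %s (only %d eligible origins across %d slides, need %d)",
                   if (lab == "1") "lesion" else "normal",
                   sum(avail), n_slides, n_per_class), call. = FALSE)
    takes <- integer(n_slides); need <- n_per_class
    while (need > 0L) {
      open <- which(avail - takes > 0L)
      quota <- ceiling(need / length(open))
      for (i in open) {
        tk <- min(quota, avail[i] - takes[i], need)
        takes[i] <- takes[i] + tk
        need <- need - tk
        if (need == 0L) break
      }
    }
    out <- list()
    for (i in which(takes > 0L)) {
      set.seed(derive_seed(seed, 5000L + 2L * i + as.integer(lab == "1")))
      pick <- sample(elig[[i]][[lab]], takes[i])
      orig <- arrayInd(pick, elig[[i]]$dims) - 1L
      img <- cohort[[i]]$image
      out <- c(out, lapply(seq_len(takes[i]), function(j) {
        r <- orig[j, 1]; cc <- orig[j, 2]
        img[(r + 1):(r + P), (cc + 1):(cc + P), , drop = FALSE]
      }))
    }
    out
  }
  p0 <- take_patches("0")
  p1 <- take_patches("1")
  train <- structure(list(patches = c(p0, p1),
                          labels = rep(c(0L, 1L), c(length(p0), length(p1))),
                          purity = purity, patch_size = P),
                     class = "labeled_patches")
  clf <- patch_classifier(train, reg_strength = reg_strength, seed = seed)
  if (!is.null(out_file)) write_classifier(clf, out_file)
  clf
}

#' Quantify every slide of a cohort
#'
#' Runs [quantify_slide()] on each slide and returns one results row per
#' slide. Slides without detectable tissue get a flagged row with a missing
#' ratio.
#'
#' @param cohort manifest path, manifest data frame, or in-memory cohort.
#' @param clf fitted classifier or path to a serialized one.
#' @param out_dir optional directory for per-slide likelihood maps (16-bit
#'   TIFF), lesion masks (0/255 PNG) and the results CSV.
#' @param ... passed to [quantify_slide()].
#' @return Data frame with columns slide_id, arm, planted_fraction (when
#'   known), A_tissue_px, A_lesion_px, ratio, n_components, theta, no_tissue.
#' @export
run_quantify <- function(cohort, clf, out_dir = NULL, ...) {
  cohort <- load_cohort(cohort)
  if (is.character(clf)) clf <- read_classifier(clf)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    res <- quantify_slide(rec$image, clf, slide_id = rec$animal_id,
                          keep_rasters = !is.null(out_dir), ...)
    q <- if (is.null(out_dir)) res else res$quant
    if (!is.null(out_dir)) {
      if (!is.null(res$map))
        write_likelihood_map(res$map, file.path(out_dir, paste0(rec$animal_id, "_map.tif")))
      write_mask(res$lesion$mask, file.path(out_dir, paste0(rec$animal_id, "_lesionpred.png")))
    }
    df <- as.data.frame(q)
    df$arm <- if (is.null(rec$arm)) NA_character_ else rec$arm
    df$planted_fraction <- if (is.null(rec$ground_truth$planted_fraction))
      NA_real_ else rec$ground_truth$planted_fraction
    df
  })
  out <- do.call(rbind, rows)
  out <- out[, c("slide_id", "arm", "planted_fraction", "A_tissue_px",
                 "A_lesion_px", "ratio", "n_components", "theta", "no_tissue")]
  if (!is.null(out_dir))
    write.csv(out, file.path(out_dir, "results.csv"), row.names = FALSE, na = "")
  out
}

#' Compare treatment arms on quantified results
#'
#' Per-arm summaries (n, affected count and incidence, mean and SD of the
#' lesion ratio; an animal is affected when it has at least one lesion
#' component after the area filter), plus the between-arm tests: pooled
#' two-tailed t (two arms), chi-square and Fisher exact on the affected
#' table (two arms), or one-way ANOVA with Bonferroni post hoc (three or
#' more arms).
#'
#' @param results data frame from [run_quantify()] (needs `arm`, `ratio`,
#'   `n_components`); rows with missing ratio are dropped with a message.
#' @param welch use Welch instead of pooled t for two arms.
#' @return An object of class `lesion_experiment`: list with `summary` (one
#'   row per arm), `tests` (list of `lq_test` objects) and `results`.
#' @export
run_compare <- function(results, welch = FALSE) {
  stopifnot(all(c("arm", "ratio", "n_components") %in% names(results)))
  drop <- is.na(results$ratio)
  if (any(drop)) {
    message(sprintf("dropping %d slide(s) without tissue", sum(drop)))
    results <- results[!drop, , drop = FALSE]
  }
  arms <- unique(results$arm)
  if (length(arms) < 2L) stop("need at least two arms to compare")
  summaries <- lapply(arms, function(a) {
    sub <- results[results$arm == a, , drop = FALSE]
    s <- summarize_arm(sub$ratio, arm_name = a)
    s$k_affected <- sum(sub$n_components >= 1L)
    s$incidence_pct <- incidence_percent(s$k_affected, s$n)
    s
  })
  sm <- do.call(rbind, lapply(summaries, function(s)
    data.frame(arm = s$arm_name, n = s$n, k_affected = s$k_affected,
               incidence_pct = s$incidence_pct, mean_ratio = s$mean,
               sd_ratio = s$sd, stringsAsFactors = FALSE)))
  tests <- list()
  if (length(arms) == 2L) {
    s1 <- summaries[[1]]; s2 <- summaries[[2]]
    tests$t_ratio <- pooled_t_test(s1$mean, s1$sd, s1$n, s2$mean, s2$sd, s2$n,
                                   welch = welch)
    a <- s1$k_affected; b <- s1$n - s1$k_affected
    cc <- s2$k_affected; d <- s2$n - s2$k_affected
    if (min(a + b, cc + d, a + cc, b + d) > 0) {
      tests$chisq_incidence <- chi_square_2x2(a, b, cc, d)
      tests$fisher_incidence <- fisher_exact_2x2(a, b, cc, d)
    }
  } else {
    gr <- split(results$ratio, results$arm)
    tests$anova_ratio <- one_way_anova(gr)
  }
  structure(list(summary = sm, tests = tests, results = results),
            class = "lesion_experiment")
}

#' @export
print.lesion_experiment <- function(x, ...) {
  cat("Arm summaries:\n")
  print(x$summary, row.names = FALSE)
  cat("\nTests:\n")
  for (t in x$tests) print(t)
  invisible(x)
}

#' Incidence table from printed per-arm counts
#'
#' Convenience for re-deriving an incidence table from (affected, total)
#' pairs, as reported in publications.
#'
#' @param counts data frame (or list of pairs) with columns `arm`, `k`, `n`.
#' @return Data frame with an added `incidence_pct` column.
#' @export
incidence_table <- function(counts) {
  counts <- as.data.frame(counts)
  counts$incidence_pct <- mapply(incidence_percent, counts$k, counts$n)
  counts
}
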