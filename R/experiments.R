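#' Train a reference classifier on dedicated training slides
#'
#' Generates `n_slides` training slides at a 30% planted fraction (so both
#' classes are plentiful) and fits the reference classifier on
#' `n_per_class` patches per class pooled across them.
#'
#' @param seed integer seed controlling the training slides and sampling.
#' @param n_slides number of training slides.
#' @param n_per_class training patches per class.
#' @param spec base [slide_spec()] for the training slides.
#' @return A fitted [patch_classifier()].
#' @export
train_reference_classifier <- function(seed = 1L, n_slides = 2L,
                                       n_per_class = 200L,
                                       spec = slide_spec()) {
  cohort <- lapply(seq_len(n_slides), function(i) {
    sp <- spec
    sp$target_lesion_fraction <- 0.3
    sp$seed <- derive_seed(seed, 300L + i)
    s <- generate_slide(sp)
    list(arm = "train", animal_id = sprintf("train_%02d", i),
         image = s$image, ground_truth = s$ground_truth)
  })
  run_train(cohort, n_per_class = n_per_class, seed = seed)
}

#' Lesion-fraction recovery experiment
#'
#' Generates `n_slides` synthetic slides at each planted fraction, quantifies
#' each with a reference classifier trained on separate slides, and reports
#' the recovered ratio and the Dice overlap between the detected and planted
#' lesion masks.
#'
#' @param fractions planted lesion fractions to probe.
#' @param n_slides slides per fraction.
#' @param seed integer master seed.
#' @param spec base [slide_spec()] (the slide conditions).
#' @param clf optional pre-trained classifier; trained via
#'   [train_reference_classifier()] when omitted.
#' @return Data frame with columns `fraction`, `slide`, `planted`, `ratio`,
#'   `dice`.
#' @export
recovery_experiment <- function(fractions = c(0, 0.05, 0.1, 0.2, 0.4),
                                n_slides = 20L, seed = 1L,
                                spec = slide_spec(), clf = NULL) {
  if (is.null(clf)) clf <- train_reference_classifier(seed, spec = spec)
  rows <- list(); k <- 0L
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    for (j in seq_len(n_slides)) {
      k <- k + 1L
      sp <- spec
      sp$target_lesion_fraction <- f
      sp$seed <- derive_seed(seed, 10000L + 100L * fi + j)
      s <- generate_slide(sp)
      res <- quantify_slide(s$image, clf, sprintf("f%03.0f_%02d", 1000 * f, j),
                            keep_rasters = TRUE)
      rows[[k]] <- data.frame(
        fraction = f, slide = j,
        planted = s$ground_truth$planted_fraction,
        ratio = res$quant$ratio,
        dice = dice_coefficient(res$lesion$mask, s$ground_truth$lesion_mask))
    }
  }
  do.call(rbind, rows)
}

#' Two-arm simulation experiment
#'
#' Emulates a two-arm design (a heavily lesioned arm vs a protected arm):
#' per replicate, per-animal lesion fractions are drawn from scaled Beta
#' laws, one slide per animal is generated and quantified, and the arms are
#' compared with the pooled two-tailed t-test on the recovered ratios.
#'
#' @param n_replicates seed replicates.
#' @param n1,n2 animals per arm.
#' @param mean1,mean2 planted mean lesion fractions of the two arms.
#' @param concentration Beta concentration (`shape1 + shape2`) of both arm
#'   laws; 60 keeps the within-arm SD near 0.05 so the design is well
#'   powered at these sample sizes.
#' @param seed integer master seed.
#' @param spec base [slide_spec()].
#' @param clf optional pre-trained classifier.
#' @return Data frame with one row per replicate: `p` (pooled-t p-value),
#'   `mean1_est`, `mean2_est` (estimated arm mean ratios), `planted1`,
#'   `planted2` (mean planted fractions actually realised).
#' @export
two_arm_experiment <- function(n_replicates = 20L, n1 = 9L, n2 = 7L,
                               mean1 = 0.20, mean2 = 0.075,
                               concentration = 60, seed = 1L,
                               spec = slide_spec(), clf = NULL) {
  if (is.null(clf)) clf <- train_reference_classifier(seed, spec = spec)
  rows <- lapply(seq_len(n_replicates), function(rep) {
    arms <- list(
      list(name = "arm_hi", n = n1, frac = dist_beta(mean1, concentration),
           spec = spec),
      list(name = "arm_lo", n = n2, frac = dist_beta(mean2, concentration),
           spec = spec))
    coh <- generate_cohort(arms, seed = derive_seed(seed, 20000L + rep))
    res <- run_quantify(coh, clf)
    cmp <- run_compare(res)
    hi <- cmp$summary[cmp$summary$arm == "arm_hi", ]
    lo <- cmp$summary[cmp$summary$arm == "arm_lo", ]
    planted <- vapply(coh, function(r) r$ground_truth$planted_fraction, 1)
    is_hi <- vapply(coh, function(r) r$arm == "arm_hi", TRUE)
    data.frame(replicate = rep, p = cmp$tests$t_ratio$p_value,
               mean1_est = hi$mean_ratio, mean2_est = lo$mean_ratio,
               planted1 = mean(planted[is_hi]), planted2 = mean(planted[!is_hi]))
  })
  do.call(rbind, rows)
}

#' Type-I calibration of the two-arm comparison
#'
#' Draws both arms' per-animal lesion burdens from the same law and runs the
#' pooled t-test, many times, to estimate the rejection rate at the 5%
#' level. This exercises the sampling and testing layers directly (the
#' imaging stages add no arm difference under the null).
#'
#' @param n_replicates number of null replicates.
#' @param n1,n2 animals per arm.
#' @param mean0,concentration the shared Beta law of both arms.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return List with `rejection_rate`, `n_replicates`, `alpha`.
#' @export
null_calibration <- function(n_replicates = 200L, n1 = 9L, n2 = 7L,
                             mean0 = 0.2, concentration = 60,
                             alpha = 0.05, seed = 1L) {
  law <- dist_beta(mean0, concentration)
  set.seed(derive_seed(seed, 777L))
  rej <- vapply(seq_len(n_replicates), function(i) {
    x <- law$draw(n1); y <- law$draw(n2)
    tt <- pooled_t_test(mean(x), sd(x), n1, mean(y), sd(y), n2)
    tt$p_value < alpha
  }, TRUE)
  list(rejection_rate = mean(rej), n_replicates = n_replicates, alpha = alpha)
}
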