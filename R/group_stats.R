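new_test_result <- function(statistic, df, p_value, test_name,
                            degenerate = FALSE, extra = list()) {
  structure(c(list(statistic = statistic, df = df, p_value = p_value,
                   test_name = test_name, degenerate = degenerate), extra),
            class = "lq_test")
}

#' @export
print.lq_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g%s\n", x$test_name,
              x$statistic, dfs, x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Incidence as a percentage, one decimal place
#'
#' `100 k / n` rounded half-up to one decimal, the convention used when
#' reporting the share of affected animals in an arm (e.g. 4 of 7 affected
#' is 57.1).
#'
#' @param k affected count, `0 <= k <= n`.
#' @param n arm size, `> 0`.
#' @return Percentage with one decimal place.
#' @export
incidence_percent <- function(k, n) {
  stopifnot(n > 0, k >= 0, k <= n)
  floor(1000 * k / n + 0.5) / 10
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Student's two-tailed t-test computable from each group's mean, sample SD
#' (n-1 denominator) and size: `sp^2 = ((n1-1)s1^2 + (n2-1)s2^2)/(n1+n2-2)`,
#' `t = (m1-m2)/(sp sqrt(1/n1 + 1/n2))`, `df = n1+n2-2`. With `welch = TRUE`
#' the unpooled statistic and Satterthwaite df are used instead. Tail
#' probabilities come from the t distribution (accurate to well below 1e-6).
#'
#' @param m1,s1,n1,m2,s2,n2 group means, sample SDs and sizes (`n >= 2`).
#' @param welch use the Welch unequal-variance form.
#' @return An object of class `lq_test` with `statistic`, `df`, `p_value`.
#'   Both SDs zero with equal means is degenerate: t = 0, p = 1, flagged.
#' @export
pooled_t_test <- function(m1, s1, n1, m2, s2, n2, welch = FALSE) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  name <- if (welch) "Welch two-sample t-test (summary)" else
    "Pooled two-sample t-test (summary)"
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2)
      return(new_test_result(0, n1 + n2 - 2, 1, name, degenerate = TRUE))
    return(new_test_result(sign(m1 - m2) * Inf, n1 + n2 - 2, 0, name,
                           degenerate = TRUE))
  }
  if (welch) {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  new_test_result(t, df, p, name,
                  extra = list(estimate = c(mean1 = m1, mean2 = m2)))
}

#' Chi-square test on a 2x2 table
#'
#' `chi^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with df = 1; no
#' continuity correction by default (set `correct = TRUE` for Yates).
#'
#' @param a,b,c,d nonnegative cell counts, rows = groups, columns = outcome;
#'   both margins must be positive.
#' @param correct apply Yates continuity correction.
#' @return An `lq_test` with `statistic`, `df = 1`, `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  check_2x2(a, b, c, d)
  N <- a + b + c + d
  num <- abs(a * d - b * c)
  if (correct) num <- max(num - N / 2, 0)
  stat <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  new_test_result(stat, 1, pchisq(stat, 1, lower.tail = FALSE),
                  if (correct) "Chi-square (Yates)" else "Chi-square")
}

check_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (min(a + b, c + d, a + c, b + d) == 0)
    stop("zero margin in 2x2 table")
  invisible(NULL)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by hypergeometric enumeration with fixed margins: the
#' sum of the probabilities of all tables no more probable than the observed
#' one. The small-count companion of [chi_square_2x2()].
#'
#' @inheritParams chi_square_2x2
#' @return An `lq_test`; `df` is `NA` (exact test).
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  check_2x2(a, b, c, d)
  row1 <- a + b; col1 <- a + c; N <- a + b + c + d
  xs <- max(0, row1 + col1 - N):min(row1, col1)
  probs <- dhyper(xs, col1, N - col1, row1)
  p_obs <- dhyper(a, col1, N - col1, row1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  new_test_result(p_obs, NA_real_, p, "Fisher exact (two-sided)")
}

#' One-way ANOVA with Bonferroni post hoc pairwise t-tests
#'
#' Classical fixed-effects decomposition: `F = MS_between / MS_within` on
#' `(k-1, N-k)` df. Post hoc contrasts are pairwise pooled t-tests with
#' Bonferroni correction. All groups constant and identical is flagged
#' degenerate (F undefined); equal means with positive spread gives F = 0,
#' p = 1.
#'
#' @param groups list of two or more numeric vectors, each of length >= 2.
#' @return An `lq_test` with `statistic` (F), `df` (length-2: between,
#'   within), `p_value`, and `posthoc` (a data frame of pairwise contrasts).
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs at least 2 values")
  ns <- vapply(groups, length, 1L)
  ms <- vapply(groups, mean, 1)
  N <- sum(ns)
  grand <- sum(ns * ms) / N
  ssb <- sum(ns * (ms - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0 && ssb == 0)
    return(new_test_result(NA_real_, c(df1, df2), NA_real_, "One-way ANOVA",
                           degenerate = TRUE))
  if (ssb == 0) {
    res <- new_test_result(0, c(df1, df2), 1, "One-way ANOVA")
  } else {
    f <- (ssb / df1) / (ssw / df2)
    res <- new_test_result(f, c(df1, df2), pf(f, df1, df2, lower.tail = FALSE),
                           "One-way ANOVA")
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  pairs <- utils::combn(k, 2)
  ph <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- pooled_t_test(ms[i1], sd(groups[[i1]]), ns[i1],
                        ms[i2], sd(groups[[i2]]), ns[i2])
    data.frame(pair = paste(names(groups)[i1], names(groups)[i2], sep = " vs "),
               t = tt$statistic, df = tt$df, p_raw = tt$p_value,
               stringsAsFactors = FALSE)
  }))
  ph$p_bonferroni <- pmin(1, ph$p_raw * ncol(pairs))
  res$posthoc <- ph
  res
}

#' Summarise one treatment arm
#'
#' Mean, sample SD (n-1 denominator) and the affected count under a
#' predicate (by default: value strictly positive, i.e. any lesion at all).
#'
#' @param values per-animal measurements (nonempty numeric).
#' @param affected_rule predicate applied per value.
#' @param arm_name optional label.
#' @return A list of class `group_summary`: `arm_name`, `n`, `k_affected`,
#'   `incidence_pct`, `mean`, `sd`.
#' @export
summarize_arm <- function(values, affected_rule = function(x) x > 0,
                          arm_name = NA_character_) {
  stopifnot(length(values) >= 1)
  n <- length(values)
  k <- sum(vapply(values, function(v) isTRUE(affected_rule(v)), TRUE))
  structure(list(arm_name = arm_name, n = n, k_affected = k,
                 incidence_pct = incidence_percent(k, n),
                 mean = mean(values),
                 sd = if (n > 1) sd(values) else 0),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("Arm %s: n = %d, affected = %d (%.1f%%), mean = %.4g, sd = %.4g\n",
              x$arm_name, x$n, x$k_affected, x$incidence_pct, x$mean, x$sd))
  invisible(x)
}
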