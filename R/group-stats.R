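# Group-level inference for the asymmetry analysis: the exact binomial
# test compares the number of asymmetric recordings against chance (0.5),
# the Wilcoxon signed-rank test compares the relative contributions of
# decreases vs increases (equivalently, one contribution against 0.5,
# since the pair sums to 1).

#' Exact binomial test for the count of asymmetric recordings
#'
#' Two-sided exact binomial p-value against success probability 0.5, using
#' the minimum-likelihood two-sided rule (outcomes no more likely than the
#' observed one are accumulated). Deterministic; delegated to
#' [stats::binom.test()], whose two-sided rule is exactly this.
#'
#' @param n_asymmetric Number of recordings classified asymmetric.
#' @param n_total Total number of recordings.
#' @return Two-sided p-value.
#' @export
#' @examples
#' binomial_asymmetry_test(44, 48)  # < 0.05
#' binomial_asymmetry_test(29, 48)  # not significant
binomial_asymmetry_test <- function(n_asymmetric, n_total) {
  if (length(n_asymmetric) != 1L || length(n_total) != 1L ||
      is.na(n_asymmetric) || is.na(n_total) ||
      n_total < 1 || n_asymmetric < 0 || n_asymmetric > n_total ||
      n_asymmetric != round(n_asymmetric) || n_total != round(n_total))
    stop("n_asymmetric must be an integer in [0, n_total], n_total >= 1",
         call. = FALSE)
  stats::binom.test(n_asymmetric, n_total, p = 0.5,
                    alternative = "two.sided")$p.value
}

#' Wilcoxon signed-rank test on relative contributions
#'
#' Paired test of the decrease vs increase contributions to a variance
#' component. Because the two contributions of a recording sum to 1, the
#' paired test reduces to a one-sample signed-rank test of the given
#' contribution against 0.5. Exact distribution for up to 25 non-zero
#' differences, normal approximation with continuity correction above
#' (ties in the absolute differences also force the approximation).
#'
#' @param contributions Numeric vector of per-recording contributions in
#'   \[0, 1\] (e.g. `c1d` or `c2i`).
#' @param exact_max Largest number of non-zero differences for which the
#'   exact null distribution is used (default 25).
#' @return Two-sided p-value; 1 when every contribution equals 0.5.
#' @export
wilcoxon_contribution_test <- function(contributions, exact_max = 25L) {
  x <- contributions[!is.na(contributions)]
  if (length(x) < 1L) stop("no non-missing contributions", call. = FALSE)
  if (any(x < 0 | x > 1))
    stop("contributions must lie in [0, 1]", call. = FALSE)
  d <- x - 0.5
  n_nonzero <- sum(d != 0)
  if (n_nonzero == 0L) return(1)
  use_exact <- n_nonzero <= exact_max
  res <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  res$p.value
}

#' Group-level asymmetry summary table
#'
#' For each group x phase x term (short, long), counts the recordings
#' classified asymmetric, tests the count against chance with the exact
#' binomial test, and tests the relative contributions (mean `c1d` for the
#' short term, mean `c2i` for the long term) against 0.5 with the Wilcoxon
#' signed-rank test. Mirrors the layout of a case-count/contribution
#' asymmetry table.
#'
#' @param descriptors Per-recording descriptor data frame (from
#'   [compute_descriptor_table()] or equivalent) containing `group`,
#'   `phase`, `sd1d`, `sd1i`, `sd2d`, `sd2i`, `c1d`, `c2i`.
#' @param alpha Significance level (default 0.05).
#' @return Data frame, one row per group x phase x term, with `n_total`,
#'   `n_asymmetric`, `fraction`, `binomial_p`, `mean_contribution`,
#'   `wilcoxon_p`, and `significant` (both tests below `alpha`). Empty
#'   group x phase cells produce no row (with a message).
#' @export
summarize_asymmetry <- function(descriptors, alpha = 0.05) {
  stopifnot(all(c("group", "phase", "sd1d", "sd1i", "sd2d", "sd2i",
                  "c1d", "c2i") %in% names(descriptors)))
  out <- list()
  for (g in unique(descriptors$group)) {
    for (ph in intersect(PHASE_LEVELS, descriptors$phase)) {
      rows <- descriptors[descriptors$group == g & descriptors$phase == ph, ]
      rows <- rows[!is.na(rows$c1d), , drop = FALSE]
      if (nrow(rows) == 0L) {
        message("summarize_asymmetry: no recordings for ", g, "/", ph)
        next
      }
      cls <- classify_asymmetry(rows)
      for (term in c("short", "long")) {
        n_asym <- if (term == "short") sum(cls$short_term_asymmetric)
                  else sum(cls$long_term_asymmetric)
        contrib <- if (term == "short") rows$c1d else rows$c2i
        bp <- binomial_asymmetry_test(n_asym, nrow(rows))
        wp <- wilcoxon_contribution_test(contrib)
        out[[length(out) + 1L]] <- data.frame(
          group = g, phase = ph, term = term,
          n_total = nrow(rows), n_asymmetric = n_asym,
          fraction = n_asym / nrow(rows),
          binomial_p = bp, mean_contribution = mean(contrib),
          wilcoxon_p = wp,
          significant = bp < alpha && wp < alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
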