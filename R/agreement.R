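#' Percent predicted V̇O2peak
#'
#' `measured / predicted * 100`, kept continuous; the integer calculator
#' display (floor rule) is obtained with [display_percent()].
#'
#' @param measured Measured V̇O2peak, mL/min (> 0).
#' @param predicted Predicted V̇O2peak, mL/min (> 0).
#' @return Continuous percent (vectorized).
#' @examples
#' pp <- percent_predicted(3560, 5209.9)  # 68.33
#' display_percent(pp)                    # 68
#' @export
percent_predicted <- function(measured, predicted) {
  stopifnot(is.numeric(measured), is.numeric(predicted))
  if (any(predicted <= 0)) stop("predicted V̇O2 must be positive")
  if (any(measured <= 0)) stop("measured V̇O2 must be positive")
  measured / predicted * 100
}

#' Classify exercise capacity at a fixed threshold
#'
#' `"normal"` iff the continuous percent-predicted value is at or above the
#' threshold (the comparison is on the continuous value, never the floored
#' display integer, so boundary behaviour is exact: 80.0 is normal, 79.99 is
#' reduced at the default threshold).
#'
#' @param pp Continuous percent-predicted values.
#' @param threshold Threshold percent in (0, 200); default the conservative
#'   fixed cut-off of 80.
#' @return Character vector, `"normal"` / `"reduced"`.
#' @export
classify_capacity <- function(pp, threshold = 80) {
  stopifnot(is.numeric(pp), length(threshold) == 1L,
            threshold > 0, threshold < 200)
  ifelse(pp >= threshold, "normal", "reduced")
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two categorical label vectors:
#' `kappa = (po - pe) / (1 - pe)` with `pe` the sum of marginal products.
#' Perfect observed agreement returns exactly 1, covering the degenerate
#' case of two identical constant raters where `pe = 1`.
#'
#' @param labels_a,labels_b Equal-length label vectors (length >= 2).
#' @return Kappa in \[-1, 1\].
#' @examples
#' cohens_kappa(c("normal","normal","reduced","reduced"),
#'              c("normal","reduced","reduced","reduced"))  # 0.5
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  n <- length(labels_a)
  if (n < 2L) stop("need at least 2 paired labels")
  po <- mean(labels_a == labels_b)
  if (po == 1) return(1)
  lev <- union(labels_a, labels_b)
  pa <- table(factor(labels_a, lev)) / n
  pb <- table(factor(labels_b, lev)) / n
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  (po - pe) / (1 - pe)
}

#' Interpretation band for a kappa value
#'
#' Conventional agreement bands, implemented as half-open intervals so every
#' value gets exactly one deterministic label: below 0.01 "none",
#' \[0.01, 0.21) "slight", \[0.21, 0.41) "fair", \[0.41, 0.61) "moderate",
#' \[0.61, 0.81) "substantial", \[0.81, 1\] "almost perfect".
#'
#' @param kappa Kappa value(s) in \[-1, 1\].
#' @return Character vector of band labels.
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.numeric(kappa), all(kappa >= -1), all(kappa <= 1))
  cuts <- c(-Inf, 0.01, 0.21, 0.41, 0.61, 0.81, Inf)
  labs <- c("none", "slight", "fair", "moderate", "substantial",
            "almost perfect")
  as.character(cut(kappa, cuts, labs, right = FALSE))
}

#' Bidirectional reclassification between two equations
#'
#' Counts subjects whose capacity class flips when switching the prediction
#' equation from `a` to `b`: `n_to_normal` (reduced under a, normal under b)
#' and `n_to_reduced` (the reverse). Directions are symmetric across the
#' pair order: `n_to_normal(a,b) == n_to_reduced(b,a)`.
#'
#' @param pp_a,pp_b Equal-length continuous percent-predicted vectors.
#' @param threshold Classification threshold.
#' @return List: `n_to_normal`, `n_to_reduced`, their cohort fractions
#'   `frac_to_normal` / `frac_to_reduced`, and `fraction_reclassified`.
#' @export
reclassification <- function(pp_a, pp_b, threshold = 80) {
  if (length(pp_a) != length(pp_b)) stop("vectors must have equal length")
  a <- classify_capacity(pp_a, threshold)
  b <- classify_capacity(pp_b, threshold)
  n <- length(a)
  n_to_normal <- sum(a == "reduced" & b == "normal")
  n_to_reduced <- sum(a == "normal" & b == "reduced")
  list(n_to_normal = n_to_normal, n_to_reduced = n_to_reduced,
       frac_to_normal = if (n) n_to_normal / n else 0,
       frac_to_reduced = if (n) n_to_reduced / n else 0,
       fraction_reclassified = if (n) (n_to_normal + n_to_reduced) / n else 0)
}

#' Quartile summary of absolute percent-predicted differences
#'
#' Median and quartiles of `|pp_a - pp_b|` on the continuous percent scale.
#' Quartiles use the linear-interpolation convention (R quantile type 7);
#' the convention is recorded in the result since these are reported values.
#'
#' @inheritParams reclassification
#' @return List: `ad_median`, `ad_q1`, `ad_q3`, `convention`.
#' @export
absolute_difference_summary <- function(pp_a, pp_b) {
  if (length(pp_a) != length(pp_b)) stop("vectors must have equal length")
  if (!length(pp_a)) stop("need at least one pair")
  ad <- abs(pp_a - pp_b)
  q <- stats::quantile(ad, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(ad_median = q[2], ad_q1 = q[1], ad_q3 = q[3],
       convention = "linear interpolation (type 7)")
}

#' Friedman rank test across equations with Kendall's W
#'
#' Nonparametric test that the k equations' percent-predicted values share a
#' common location, computed from the classical rank-sum statistic on
#' within-subject ranks (mean ranks on ties, no tie correction):
#' `chi2 = 12 / (n k (k+1)) * sum(Rj^2) - 3 n (k+1)`, referred to a
#' chi-squared distribution with k-1 df. Kendall's W effect size is
#' `chi2 / (n (k-1))`.
#'
#' @param pp_matrix Numeric matrix, n subjects x k equations (n >= 2,
#'   k >= 3, no missing cells — no imputation is performed).
#' @return List of class `"friedman_vo2"`: `chi2`, `df`, `p_value`,
#'   `kendall_w`, `n`, `k`.
#' @export
friedman_test <- function(pp_matrix) {
  pp_matrix <- as.matrix(pp_matrix)
  n <- nrow(pp_matrix); k <- ncol(pp_matrix)
  if (n < 2L || k < 3L) stop("need at least 2 subjects and 3 equations")
  if (anyNA(pp_matrix)) stop("missing cells are not allowed (no imputation)")
  ranks <- t(apply(pp_matrix, 1L, rank))
  Rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  chi2 <- max(chi2, 0)  # guard tiny negative from floating point
  structure(list(chi2 = chi2, df = k - 1L,
                 p_value = stats::pchisq(chi2, k - 1L, lower.tail = FALSE),
                 kendall_w = chi2 / (n * (k - 1L)), n = n, k = k),
            class = "friedman_vo2")
}

#' Kendall's W from a Friedman statistic
#'
#' @param chi2 Friedman chi-squared statistic.
#' @param n Number of subjects.
#' @param k Number of related samples (equations).
#' @return Effect size in \[0, 1\].
#' @examples
#' kendall_w(936.0, 305, 6)  # 0.61
#' @export
kendall_w <- function(chi2, n, k) {
  stopifnot(chi2 >= 0, n >= 1, k >= 2)
  chi2 / (n * (k - 1))
}

#' @export
print.friedman_vo2 <- function(x, ...) {
  cat(sprintf(
    "Friedman rank test: chi2(%d) = %.1f, p = %.3g, Kendall's W = %.2f (n = %d, k = %d)\n",
    x$df, x$chi2, x$p_value, x$kendall_w, x$n, x$k))
  invisible(x)
}

#' All-pairs post hoc comparisons with Bonferroni adjustment
#'
#' Paired Wilcoxon signed-rank tests on percent-predicted differences for
#' every pair of equations, Bonferroni-adjusted over the k(k-1)/2 pairs
#' (`p_adj = min(1, p_raw * n_pairs)`). A pair whose differences are all
#' zero gets p = 1 by convention. The method name is recorded in the output
#' so an alternative exact all-pairs procedure can be swapped in and remain
#' traceable.
#'
#' @inheritParams friedman_test
#' @return Data frame with one row per pair: `from`, `to`, `statistic`,
#'   `p_raw`, `p_adj`, `method`.
#' @export
pairwise_posthoc <- function(pp_matrix) {
  pp_matrix <- as.matrix(pp_matrix)
  n <- nrow(pp_matrix); k <- ncol(pp_matrix)
  if (n < 2L || k < 3L) stop("need at least 2 subjects and 3 equations")
  if (anyNA(pp_matrix)) stop("missing cells are not allowed")
  ids <- colnames(pp_matrix) %||% paste0("eq", seq_len(k))
  pairs <- utils::combn(k, 2L)
  res <- apply(pairs, 2L, function(ij) {
    x <- pp_matrix[, ij[1]]; y <- pp_matrix[, ij[2]]
    if (all(x == y)) return(c(NA_real_, 1))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    c(unname(wt$statistic), wt$p.value)
  })
  out <- data.frame(
    from = ids[pairs[1, ]], to = ids[pairs[2, ]],
    statistic = res[1, ], p_raw = res[2, ],
    p_adj = stats::p.adjust(res[2, ], method = "bonferroni"),
    method = "paired Wilcoxon signed-rank, Bonferroni",
    stringsAsFactors = FALSE
  )
  out
}
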