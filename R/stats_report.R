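## Study-style statistical summaries: weighted Cohen's kappa for two-rater
## ordinal agreement, and thin wrappers for paired comparisons.

landis_koch_band <- function(kappa) {
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

#' Two-rater ordinal rating table
#'
#' @param rater_a,rater_b ordinal scores per item (numeric, e.g. a 5-point
#'   scale; half-point scores are supported by listing them in
#'   `scale_levels`)
#' @param scale_levels ordered category values; default the sorted union of
#'   the observed scores
#' @return a `rating_table`
#' @export
rating_table <- function(rater_a, rater_b, scale_levels = NULL) {
  if (length(rater_a) != length(rater_b)) stop("raters must score the same items")
  if (length(rater_a) < 2L) stop("at least two items are required")
  if (is.null(scale_levels)) scale_levels <- sort(unique(c(rater_a, rater_b)))
  if (!all(rater_a %in% scale_levels) || !all(rater_b %in% scale_levels)) {
    stop("all scores must lie on the declared scale")
  }
  structure(list(rater_a = rater_a, rater_b = rater_b,
                 scale_levels = scale_levels),
            class = "rating_table")
}

#' Weighted Cohen's kappa with large-sample confidence interval
#'
#' Chance-corrected agreement for two raters on an ordinal scale with
#' distance-dependent disagreement weights:
#' `kappa = 1 - sum(w * O) / sum(w * E)` with `O` the observed contingency
#' proportions, `E` the chance-expected proportions from the marginals, and
#' `w_ij = |i - j| / (k - 1)` (linear, default) or its square (quadratic).
#' The 95% CI uses the standard large-sample variance of the weighted kappa
#' estimate (Fleiss-Cohen-Everitt form). The Landis-Koch interpretation
#' band of the point estimate (0.61-0.8 "substantial" etc.) is attached.
#'
#' A rater who uses a single category has undefined kappa and triggers an
#' error rather than a silent 0.
#'
#' @param t a [rating_table()]
#' @param weights `"linear"` or `"quadratic"`
#' @param conf_level confidence level (default 0.95)
#' @return list: `kappa`, `ci_low`, `ci_high`, `se`, `band`, `weights`, `n`
#' @export
weighted_kappa <- function(t, weights = c("linear", "quadratic"),
                           conf_level = 0.95) {
  stopifnot(inherits(t, "rating_table"))
  weights <- match.arg(weights)
  lv <- t$scale_levels
  k <- length(lv)
  fa <- factor(t$rater_a, levels = lv)
  fb <- factor(t$rater_b, levels = lv)
  if (length(unique(t$rater_a)) < 2L || length(unique(t$rater_b)) < 2L) {
    stop("kappa undefined: a rater used a single category (zero variance)")
  }
  n <- length(fa)
  O <- table(fa, fb) / n                 # observed proportions
  pa <- rowSums(O); pb <- colSums(O)     # marginals
  E <- outer(pa, pb)                     # chance-expected proportions
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (weights == "linear") d else d^2      # disagreement weights
  denom <- sum(w * E)
  if (denom == 0) stop("kappa undefined: no chance-expected disagreement")
  kap <- 1 - sum(w * O) / denom

  # large-sample variance via agreement weights wa = 1 - w (w_max = 1)
  wa <- 1 - w
  po <- sum(wa * O); pe <- sum(wa * E)
  wbar_i <- as.vector(wa %*% pb)   # row-wise expected agreement weight
  wbar_j <- as.vector(pa %*% wa)
  term <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    term[i, j] <- O[i, j] *
      (wa[i, j] * (1 - pe) - (wbar_i[i] + wbar_j[j]) * (1 - po))^2
  }
  var_k <- (sum(term) - (po * pe - 2 * pe + po)^2) / (n * (1 - pe)^4)
  se <- sqrt(max(var_k, 0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kap, ci_low = kap - zq * se, ci_high = kap + zq * se,
       se = se, band = landis_koch_band(kap), weights = weights, n = n)
}

#' Paired comparison of two measurement arms
#'
#' Thin, logged wrapper over the standard routines (`t.test` with
#' `paired = TRUE`, `wilcox.test` paired signed-rank) so pipeline reports
#' carry the per-arm mean, SD and range alongside the test. Identical arms
#' return statistic 0 and p = 1 for the t-test; the signed-rank test is
#' undefined on all-zero differences and errors.
#'
#' @param values_a,values_b paired measurements (equal length >= 2)
#' @param test `"paired_t"` or `"wilcoxon_signed_rank"`
#' @return list: `statistic`, `p_value`, `test`, and per-arm summaries
#'   (`mean`, `sd`, `range`)
#' @export
paired_compare <- function(values_a, values_b,
                           test = c("paired_t", "wilcoxon_signed_rank")) {
  test <- match.arg(test)
  if (length(values_a) != length(values_b)) stop("arms must have equal length")
  if (length(values_a) < 2L) stop("at least two pairs are required")
  d <- values_a - values_b
  if (test == "paired_t") {
    if (all(d == 0)) {
      res <- list(statistic = 0, p_value = 1)
    } else if (stats::sd(d) == 0) {
      # constant non-zero difference: degenerate limit of the t statistic
      res <- list(statistic = sign(mean(d)) * Inf, p_value = 0)
    } else {
      ht <- stats::t.test(values_a, values_b, paired = TRUE)
      res <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
    }
  } else {
    if (all(d == 0)) stop("signed-rank test undefined: all paired differences are zero")
    ht <- stats::wilcox.test(values_a, values_b, paired = TRUE, exact = FALSE)
    res <- list(statistic = unname(ht$statistic), p_value = ht$p.value)
  }
  c(res, list(
    test = test,
    arm_a = list(mean = mean(values_a), sd = stats::sd(values_a),
                 range = range(values_a)),
    arm_b = list(mean = mean(values_b), sd = stats::sd(values_b),
                 range = range(values_b))
  ))
}
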