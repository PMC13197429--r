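#' Permutation null distribution of the weighted F1
#'
#' Holds the predictions fixed and repeatedly permutes the ground-truth
#' labels (multi-label sets are shuffled intact, as units), recomputing the
#' weighted F1 each time. The resulting distribution is the by-chance
#' performance the observed score is compared against.
#'
#' @param predictions A predictions tibble ([make_predictions()]).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return Numeric vector of `n_perm` weighted-F1 values.
#' @export
permutation_null <- function(predictions, n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 1, nrow(predictions) >= 1)
  codes <- prediction_codes(predictions)
  n <- nrow(predictions)
  pred <- codes$pred
  has_pred <- !is.na(pred)
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      tm <- codes$truth_mat[perm, , drop = FALSE]
      first <- codes$first[perm]
      correct <- rep(FALSE, n)
      correct[has_pred] <- tm[cbind(which(has_pred), pred[has_pred])]
      prf1_from_codes(pred, first, correct)$f1
    }, numeric(1))
  })
}

#' Z-score significance of a score against a null distribution
#'
#' Standardizes the observed score against the null, `z = (x - mu) / sigma`,
#' and reports the two-sided p-value from the standard normal tail. The
#' empirical permutation-rank p-value,
#' `(1 + #{null >= x}) / (n_perm + 1)` (one-sided, exceedance), is reported
#' alongside. A degenerate null (`sigma = 0`) is flagged: `p = 1` when the
#' score equals the null mean, otherwise `p = 0` with `z` infinite.
#'
#' @param x Observed score.
#' @param null Numeric null distribution (e.g. [permutation_null()]).
#' @return One-row tibble: `x`, `mu`, `sigma`, `z`, `p`, `p_empirical`,
#'   `n_perm`, `degenerate`.
#' @export
z_and_p <- function(x, null) {
  if (length(null) == 0) abort("Null distribution is empty.")
  mu <- mean(null)
  sigma <- sd(null)
  if (length(null) == 1) sigma <- 0
  degenerate <- !is.finite(sigma) || sigma == 0
  if (degenerate) {
    z <- if (x == mu) 0 else sign(x - mu) * Inf
    p <- if (x == mu) 1 else 0
  } else {
    z <- (x - mu) / sigma
    p <- 2 * pnorm(-abs(z))
  }
  tibble(
    x = x, mu = mu, sigma = if (degenerate) 0 else sigma, z = z, p = p,
    p_empirical = (1 + sum(null >= x)) / (length(null) + 1),
    n_perm = length(null), degenerate = degenerate
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction across a family of p-values
#' (one per model-prompt combination, in the usual workflow). Thin,
#' validating wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Two-proportion z-test
#'
#' Pooled two-sided z-test for the difference of two independent
#' proportions `k1/n1` and `k2/n2` (used for correctness/completeness
#' proportions in reasoning-evaluation tables).
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return One-row tibble: `p1`, `p2`, `z`, `p`.
#' @examples
#' two_proportion_z(46, 81, 24, 81)
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  if (se == 0) {
    z <- 0
    p <- 1
  } else {
    z <- (p1 - p2) / se
    p <- 2 * pnorm(-abs(z))
  }
  tibble(p1 = p1, p2 = p2, z = z, p = p)
}

#' Full permutation significance report for a prediction set
#'
#' Convenience wrapper: observed weighted F1, permutation null, z-score,
#' normal and empirical p-values.
#'
#' @inheritParams permutation_null
#' @return One-row tibble (see [z_and_p()]).
#' @export
significance_report <- function(predictions, n_perm = 999L, seed = 1L) {
  x <- weighted_prf1(predictions)$f1
  z_and_p(x, permutation_null(predictions, n_perm = n_perm, seed = seed))
}
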