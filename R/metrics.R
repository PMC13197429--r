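#' Argmax prediction from a likelihood vector
#'
#' The predicted seizure onset zone is the region with the highest stated
#' likelihood. Ties are broken by the canonical region order. An all-zero
#' vector (a failed parse) yields a designated no-prediction, treated
#' downstream as incorrect with probability 0.
#'
#' @param likelihoods Named 7-vector of percent likelihoods.
#' @return A list: `region` (canonical name, or `NA` for no-prediction) and
#'   `p` (the predicted-class likelihood rescaled to \[0, 1\]).
#' @examples
#' predict_region(c(40, 30, 5, 5, 5, 10, 5))
#' @export
predict_region <- function(likelihoods) {
  v <- as_region_vector(likelihoods)
  if (all(v == 0)) {
    return(list(region = NA_character_, p = 0))
  }
  i <- which.max(v) # first maximum = canonical-order tie-break
  list(region = soz_regions()[i], p = min(1, v[[i]] / 100))
}

#' Entropy-based confidence of a likelihood vector
#'
#' The elicited likelihoods are renormalized to a probability distribution
#' and scored with the Shannon entropy in bits,
#' `H = -sum(p * log2(p))` (with `0 * log 0 = 0`), which ranges from 0
#' (all mass on one region) to `log2(7) = 2.807` (uniform over the seven
#' regions). Confidence is one minus the normalized entropy,
#' `C = 1 - H / log2(7)`: 1 means fully concentrated, 0 uniform. A vector
#' with no positive mass is assigned `C = 0` by convention.
#'
#' @param likelihoods Named 7-vector of percent likelihoods (need not sum
#'   to 100; it is rescaled).
#' @return A list: `entropy` (bits), `norm_entropy`, `confidence`.
#' @examples
#' confidence_score(rep(100 / 7, 7)) # uniform: H = 2.807, C = 0
#' confidence_score(c(100, 0, 0, 0, 0, 0, 0)) # one-hot: H = 0, C = 1
#' @export
confidence_score <- function(likelihoods) {
  v <- as_region_vector(likelihoods)
  hmax <- log2(7)
  if (sum(v) <= 0) {
    return(list(entropy = hmax, norm_entropy = 1, confidence = 0))
  }
  p <- v / sum(v)
  p <- p[p > 0]
  h <- max(0, -sum(p * log2(p))) # max() also drops IEEE -0 for one-hot input
  list(entropy = h, norm_entropy = h / hmax, confidence = 1 - h / hmax)
}

#' Build the per-entry prediction table
#'
#' Joins parsed responses to the corpus ground truth and derives, per
#' entry: the argmax prediction, its correctness (a prediction is correct
#' iff it lies in the possibly multi-label truth set), the probability used
#' for calibration, and the entropy-based confidence.
#'
#' @param parsed A parsed-response tibble from [parse_responses()] (one row
#'   per entry; aggregate self-consistency chains with [median_vote()]
#'   first, e.g. via [vote_chains()]).
#' @param corpus The corpus tibble the responses answer.
#' @param prob Which likelihood enters calibration and the Brier score:
#'   `"predicted"` (default) pairs the argmax region's stated likelihood
#'   with the right/wrong outcome; `"true"` uses the likelihood assigned to
#'   the (best-matching) truth region.
#' @return A predictions tibble: `id`, `predicted`, `truth`, `correct`,
#'   `p_pred`, `confidence`, `status`, `word_count`.
#' @export
make_predictions <- function(parsed, corpus, prob = c("predicted", "true")) {
  prob <- match.arg(prob)
  idx <- match(parsed$entry_id, corpus$id)
  if (anyNA(idx)) {
    abort(sprintf(
      "Responses reference unknown entry id(s): %s",
      paste(head(unique(parsed$entry_id[is.na(idx)]), 5), collapse = ", ")
    ))
  }
  truth <- corpus$truth[idx]
  preds <- map(parsed$likelihoods, predict_region)
  predicted <- map_chr(preds, "region")
  correct <- map2_lgl(predicted, truth, function(p, t) !is.na(p) && p %in% t)
  p_pred <- if (prob == "predicted") {
    map_dbl(preds, "p")
  } else {
    map2_dbl(parsed$likelihoods, truth, function(v, t) min(1, max(v[t]) / 100))
  }
  tibble(
    id = parsed$entry_id,
    predicted = predicted,
    truth = truth,
    correct = correct,
    p_pred = p_pred,
    confidence = map_dbl(parsed$likelihoods, function(v) confidence_score(v)$confidence),
    status = if ("status" %in% names(parsed)) parsed$status else "ok",
    word_count = corpus$word_count[idx]
  )
}

# ---- weighted precision / recall / F1 -------------------------------------

# integer encodings used by the fast scoring path (and the permutation null)
prediction_codes <- function(predictions) {
  regions <- soz_regions()
  n <- nrow(predictions)
  truth_mat <- matrix(FALSE, n, 7)
  for (i in seq_len(n)) truth_mat[i, match(predictions$truth[[i]], regions)] <- TRUE
  list(
    pred = match(predictions$predicted, regions), # NA = no-prediction
    first = match(map_chr(predictions$truth, 1), regions),
    truth_mat = truth_mat
  )
}

# weighted P/R/F1 from integer-coded predictions and effective truth labels.
# Multi-label entries credit the matched truth region when correct;
# otherwise the first-listed truth region takes the false negative and the
# predicted region the false positive.
prf1_from_codes <- function(pred, first, correct) {
  truth_eff <- ifelse(correct, pred, first)
  ok <- !is.na(pred) & pred == truth_eff
  tp <- tabulate(truth_eff[ok], nbins = 7)
  pred_n <- tabulate(pred, nbins = 7)
  supp <- tabulate(truth_eff, nbins = 7)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(supp > 0, tp / supp, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  w <- supp / sum(supp)
  list(
    per_class = tibble(
      region = soz_regions(), support = supp,
      precision = precision, recall = recall, f1 = f1
    ),
    precision = sum(w * precision), recall = sum(w * recall), f1 = sum(w * f1)
  )
}

#' Support-weighted precision, recall, and F1
#'
#' Per-class one-vs-rest precision, recall, and F1 are averaged with
#' weights proportional to class support, which accommodates the strong
#' class imbalance of semiology corpora. See `prob`/multi-label handling in
#' [make_predictions()]: an entry counts for the truth region it matched
#' when correct, and for its first-listed truth region otherwise.
#'
#' @param predictions A predictions tibble ([make_predictions()]).
#' @return One-row tibble: `precision`, `recall`, `f1` (fractions in
#'   \[0, 1\]).
#' @export
weighted_prf1 <- function(predictions) {
  if (nrow(predictions) == 0) abort("Cannot score an empty prediction set.")
  codes <- prediction_codes(predictions)
  res <- prf1_from_codes(codes$pred, codes$first, predictions$correct)
  tibble(precision = res$precision, recall = res$recall, f1 = res$f1)
}

#' Per-class metrics behind the weighted averages
#' @inheritParams weighted_prf1
#' @return Tibble with one row per region: `region`, `support`,
#'   `precision`, `recall`, `f1`.
#' @export
per_class_metrics <- function(predictions) {
  codes <- prediction_codes(predictions)
  prf1_from_codes(codes$pred, codes$first, predictions$correct)$per_class
}

# ---- calibration ----------------------------------------------------------

#' Reliability bins
#'
#' Predictions are partitioned into `bins` equal-width probability bins,
#' bin `m` covering the interval `((m-1)/M, m/M]` (probability 0, i.e. a
#' failed parse, is kept in bin 1). Per bin the empirical accuracy
#' (fraction of positives) and the mean stated probability are reported;
#' perfect calibration puts every occupied bin on the diagonal.
#'
#' @param predictions A predictions tibble.
#' @param bins Number of bins `M` (default 10; must be at least 2).
#' @return Tibble with one row per bin: `bin`, `lower`, `upper`, `n`,
#'   `conf` (mean probability), `f_pos` (fraction correct); empty bins have
#'   `n = 0` and `NA` summaries.
#' @export
reliability <- function(predictions, bins = 10L) {
  if (bins < 2) abort("Reliability requires at least 2 bins.")
  p <- predictions$p_pred
  stopifnot(all(p >= 0 & p <= 1))
  b <- pmin(bins, pmax(1L, ceiling(p * bins)))
  tibble(bin = seq_len(bins)) |>
    mutate(lower = (bin - 1) / bins, upper = bin / bins) |>
    left_join(
      tibble(bin = b, p = p, correct = predictions$correct) |>
        group_by(bin) |>
        summarise(n = n(), conf = mean(p), f_pos = mean(correct), .groups = "drop"),
      by = "bin"
    ) |>
    mutate(n = ifelse(is.na(n), 0L, n))
}

#' Brier score
#'
#' Mean squared difference between the stated probability and the binary
#' correctness outcome, `B_s = mean((p - y)^2)`; lower is better
#' calibrated.
#'
#' @param predictions A predictions tibble.
#' @return Numeric scalar in \[0, 1\].
#' @export
brier <- function(predictions) {
  stopifnot(nrow(predictions) > 0)
  mean((predictions$p_pred - as.numeric(predictions$correct))^2)
}

# ---- bootstrap ------------------------------------------------------------

#' Percentile bootstrap of a per-entry score
#'
#' @param scores Numeric vector of per-entry scores.
#' @param B Number of resamples (default 999).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; resampling is deterministic given it.
#' @param stat Aggregate statistic (default `mean`).
#' @return One-row tibble: `estimate`, `boot_mean`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(scores, B = 999L, level = 0.95, seed = 1L, stat = mean) {
  if (length(scores) == 0) abort("Cannot bootstrap an empty score vector.")
  stopifnot(B >= 1)
  n <- length(scores)
  withr::with_seed(seed, {
    stats <- vapply(seq_len(B), function(b) stat(scores[sample.int(n, n, replace = TRUE)]), numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- unname(quantile(stats, c(alpha, 1 - alpha)))
  tibble(
    estimate = stat(scores), boot_mean = mean(stats),
    lower = qs[1], upper = qs[2]
  )
}

#' Percentile bootstrap of an aggregate prediction metric
#'
#' Resamples entries (rows of the prediction table) and recomputes the
#' metric, matching a bootstrap over the corpus entries.
#'
#' @param predictions A predictions tibble.
#' @param metric Function mapping a predictions tibble to a scalar, e.g.
#'   `function(p) weighted_prf1(p)$f1`.
#' @inheritParams bootstrap_ci
#' @return One-row tibble: `estimate`, `boot_mean`, `lower`, `upper`.
#' @export
bootstrap_metric <- function(predictions, metric, B = 999L, level = 0.95, seed = 1L) {
  if (nrow(predictions) == 0) abort("Cannot bootstrap an empty prediction set.")
  n <- nrow(predictions)
  withr::with_seed(seed, {
    stats <- vapply(seq_len(B), function(b) {
      metric(predictions[sample.int(n, n, replace = TRUE), ])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- unname(quantile(stats, c(alpha, 1 - alpha)))
  tibble(
    estimate = metric(predictions), boot_mean = mean(stats),
    lower = qs[1], upper = qs[2]
  )
}

# ---- full evaluation ------------------------------------------------------

#' Evaluate a prediction table
#'
#' One call computing the full metric set: weighted precision/recall/F1
#' with a bootstrap confidence interval, mean entropy-based confidence,
#' reliability bins, and the Brier score.
#'
#' @param predictions A predictions tibble ([make_predictions()]).
#' @param bins Reliability bin count `M`.
#' @param n_boot Bootstrap resamples for the F1 interval (default 999).
#' @param level Bootstrap confidence level.
#' @param seed Seed for the bootstrap.
#' @return An object of class `soz_eval`; see [glance.soz_eval()] and
#'   [tidy.soz_eval()].
#' @examples
#' corp <- generate_corpus(corpus_params(n = 100, seed = 1))
#' res <- evaluate_responses(corp, backend = mock_backend(), n_boot = 99)
#' glance(res)
#' @export
evaluate_predictions <- function(predictions, bins = 10L, n_boot = 999L,
                                 level = 0.95, seed = 1L) {
  prf <- weighted_prf1(predictions)
  ci <- bootstrap_metric(predictions, function(p) weighted_prf1(p)$f1,
    B = n_boot, level = level, seed = seed
  )
  structure(list(
    predictions = predictions,
    precision = prf$precision, recall = prf$recall, f1 = prf$f1,
    f1_ci = ci,
    accuracy = mean(predictions$correct),
    mean_confidence = mean(predictions$confidence),
    brier = brier(predictions),
    calibration = reliability(predictions, bins = bins),
    per_class = per_class_metrics(predictions),
    n = nrow(predictions), bins = as.integer(bins),
    n_boot = as.integer(n_boot), level = level, seed = as.integer(seed)
  ), class = "soz_eval")
}

#' @export
print.soz_eval <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<soz_eval> n = %d\n",
      "  weighted F1: %.4f (%d%% CI %.4f-%.4f), precision %.4f, recall %.4f\n",
      "  accuracy: %.4f | mean confidence: %.4f | Brier: %.4f\n"
    ),
    x$n, x$f1, round(100 * x$level), x$f1_ci$lower, x$f1_ci$upper,
    x$precision, x$recall, x$accuracy, x$mean_confidence, x$brier
  ))
  invisible(x)
}

#' Glance at an evaluation
#' @param x A `soz_eval`.
#' @param ... Unused.
#' @return One-row tibble with the headline metrics.
#' @method glance soz_eval
#' @export
glance.soz_eval <- function(x, ...) {
  tibble(
    n = x$n, precision = x$precision, recall = x$recall, f1 = x$f1,
    f1_lower = x$f1_ci$lower, f1_upper = x$f1_ci$upper,
    accuracy = x$accuracy, mean_confidence = x$mean_confidence,
    brier = x$brier
  )
}

#' Tidy per-class metrics of an evaluation
#' @param x A `soz_eval`.
#' @param ... Unused.
#' @return Tibble with one row per region.
#' @method tidy soz_eval
#' @export
tidy.soz_eval <- function(x, ...) x$per_class

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
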