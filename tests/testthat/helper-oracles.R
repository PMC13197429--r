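# Independent brute-force oracles, deliberately written as plain loops with
# no shared code with the implementation they check.

# weighted precision/recall/F1 from explicit per-class confusion counts.
# pred: character vector (NA = no prediction); truth: list of character
# vectors. Multi-label rule: a correct prediction counts for the matched
# region; an incorrect one counts a false negative for the first-listed
# truth region.
oracle_prf1 <- function(pred, truth) {
  regions <- soz_regions()
  eff <- character(length(pred))
  for (i in seq_along(pred)) {
    eff[i] <- if (!is.na(pred[i]) && pred[i] %in% truth[[i]]) pred[i] else truth[[i]][1]
  }
  prec <- rec <- f1 <- supp <- numeric(length(regions))
  for (k in seq_along(regions)) {
    r <- regions[k]
    tp <- sum(!is.na(pred) & pred == r & eff == r)
    fp <- sum(!is.na(pred) & pred == r & eff != r)
    fn <- sum(eff == r & (is.na(pred) | pred != r))
    supp[k] <- sum(eff == r)
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  w <- supp / sum(supp)
  list(precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}

# self-consistency winner by direct transcription of the median/abs-deviation
# voting rule on a 7 x 5 matrix
oracle_vote <- function(mat) {
  sums <- numeric(5)
  for (j in 1:5) {
    s <- 0
    for (i in 1:7) {
      med <- sort(mat[i, ])[3] # middle order statistic of 5
      s <- s + abs(mat[i, j] - med)
    }
    sums[j] <- s
  }
  which(sums == min(sums))[1]
}

# random predictions tibble over a given corpus (labels independent of truth)
random_predictions <- function(corpus, seed) {
  withr::with_seed(seed, {
    pred <- sample(soz_regions(), nrow(corpus), replace = TRUE)
    tibble::tibble(
      id = corpus$id,
      predicted = pred,
      truth = corpus$truth,
      correct = mapply(function(p, t) p %in% t, pred, corpus$truth),
      p_pred = runif(nrow(corpus)),
      confidence = runif(nrow(corpus))
    )
  })
}

# tiny deterministic corpus with known composition
toy_corpus <- function(truths, texts = NULL) {
  n <- length(truths)
  sozloc::as_corpus(tibble::tibble(
    id = sprintf("t%02d", seq_len(n)),
    text = texts %||% rep("epigastric aura rising", n),
    language = "en",
    truth = truths
  ), rules = NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
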