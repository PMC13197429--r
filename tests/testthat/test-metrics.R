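test_that("argmax prediction follows canonical-order tie-breaking", {
  expect_equal(predict_region(c(40, 30, 5, 5, 5, 10, 5))$region, "Temporal Lobe")
  expect_equal(predict_region(c(30, 30, 8, 8, 8, 8, 8))$region, "Temporal Lobe")
  expect_equal(predict_region(c(5, 8, 8, 30, 30, 8, 8))$region, "Parietal Lobe")
  none <- predict_region(rep(0, 7))
  expect_true(is.na(none$region))
  expect_equal(none$p, 0)
  expect_equal(predict_region(c(80, 5, 5, 5, 5, 0, 0))$p, 0.8)
})

test_that("entropy and confidence hit the analytic extremes and middle case", {
  u <- confidence_score(rep(100 / 7, 7))
  expect_equal(u$entropy, log2(7))
  expect_equal(round(u$entropy, 3), 2.807)
  expect_equal(u$confidence, 0)
  one <- confidence_score(c(100, 0, 0, 0, 0, 0, 0))
  expect_equal(one$entropy, 0)
  expect_equal(one$confidence, 1)
  half <- confidence_score(c(50, 50, 0, 0, 0, 0, 0))
  expect_equal(half$entropy, 1)
  expect_equal(half$confidence, 1 - 1 / log2(7), tolerance = 1e-12)
  expect_equal(round(half$confidence, 4), 0.6438)
  # scaling invariance: entropy uses the renormalized vector
  expect_equal(
    confidence_score(c(5, 5, 0, 0, 0, 0, 0))$entropy,
    confidence_score(c(50, 50, 0, 0, 0, 0, 0))$entropy
  )
  # zero-mass convention
  expect_equal(confidence_score(rep(0, 7))$confidence, 0)
  # C = 1 - H/log2(7) exactly, on random vectors
  withr::with_seed(1, {
    for (i in 1:50) {
      cs <- confidence_score(runif(7, 0, 100))
      expect_equal(cs$confidence, 1 - cs$entropy / log2(7), tolerance = 1e-12)
    }
  })
})

test_that("weighted F1 reproduces the hand-computed constant-predictor toy", {
  # 10 entries, 6 class A (Temporal) and 4 class B (Frontal), always predict A:
  # A: P = 6/10, R = 1, F1 = 12/16; B: F1 = 0 -> weighted F1 = 0.6*(12/16) = 0.45
  corp <- toy_corpus(c(rep(list("Temporal Lobe"), 6), rep(list("Frontal Lobe"), 4)))
  preds <- tibble::tibble(
    id = corp$id, predicted = "Temporal Lobe", truth = corp$truth,
    correct = vapply(corp$truth, function(t) "Temporal Lobe" %in% t, logical(1)),
    p_pred = 1, confidence = 1
  )
  res <- weighted_prf1(preds)
  expect_equal(res$f1, 0.45)
  expect_equal(res$recall, 0.6)
  expect_equal(res$precision, 0.36)
  # all correct on singleton truths -> perfect scores
  perfect <- preds
  perfect$predicted <- vapply(corp$truth, `[`, character(1), 1)
  perfect$correct <- TRUE
  expect_equal(weighted_prf1(perfect)$f1, 1.0)
  expect_error(weighted_prf1(preds[0, ]), "empty")
})

test_that("weighted metrics agree with the brute-force confusion oracle", {
  corp <- generate_corpus(corpus_params(n = 500, seed = 14))
  for (s in 1:5) {
    preds <- random_predictions(corp, seed = 100 + s)
    got <- weighted_prf1(preds)
    want <- oracle_prf1(preds$predicted, preds$truth)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
  }
  # including no-predictions (failed parses)
  preds <- random_predictions(corp, seed = 999)
  preds$predicted[1:25] <- NA_character_
  preds$correct[1:25] <- FALSE
  expect_equal(
    weighted_prf1(preds)$f1,
    oracle_prf1(preds$predicted, preds$truth)$f1,
    tolerance = 1e-12
  )
})

test_that("reliability bins cover (0,1] with boundary and degenerate cases", {
  mk <- function(p, correct) {
    tibble::tibble(
      id = as.character(seq_along(p)), predicted = "Temporal Lobe",
      truth = rep(list("Temporal Lobe"), length(p)),
      correct = correct, p_pred = p, confidence = p
    )
  }
  # all p = 1, all correct -> only the last bin is occupied, on the diagonal
  r <- reliability(mk(rep(1, 20), rep(TRUE, 20)), bins = 10)
  expect_equal(sum(r$n), 20)
  expect_equal(r$n[10], 20)
  expect_equal(r$f_pos[10], 1)
  expect_equal(r$conf[10], 1)
  # constant p = 0.5, half correct
  r2 <- reliability(mk(rep(0.5, 40), rep(c(TRUE, FALSE), 20)), bins = 10)
  occupied <- which(r2$n > 0)
  expect_equal(occupied, 5L) # 0.5 lies in ((m-1)/M, m/M] with m = 5
  expect_equal(r2$f_pos[5], 0.5)
  expect_equal(r2$conf[5], 0.5)
  # p = 0 (failed parse) stays in the bottom bin rather than vanishing
  r3 <- reliability(mk(c(0, 1), c(FALSE, TRUE)), bins = 10)
  expect_equal(sum(r3$n), 2)
  expect_equal(r3$n[1], 1)
  expect_error(reliability(mk(0.5, TRUE), bins = 1), "at least 2")
})

test_that("the Brier score matches analytic cases and ignores order", {
  mk <- function(p, correct) {
    tibble::tibble(p_pred = p, correct = correct)
  }
  expect_equal(brier(mk(rep(1, 10), rep(TRUE, 10))), 0)
  expect_equal(brier(mk(rep(0.5, 10), rep(c(TRUE, FALSE), 5))), 0.25)
  withr::with_seed(2, {
    p <- runif(100)
    y <- runif(100) < 0.5
    perm <- sample(100)
    expect_equal(brier(mk(p, y)), brier(mk(p[perm], y[perm])))
  })
})

test_that("bootstrap intervals are seeded, degenerate-safe, and sized sanely", {
  expect_error(bootstrap_ci(numeric(0)), "empty")
  const <- bootstrap_ci(rep(0.7, 50), B = 199, seed = 1)
  expect_equal(const$lower, 0.7)
  expect_equal(const$upper, 0.7)
  x0 <- withr::with_seed(4, runif(100))
  expect_identical(
    bootstrap_ci(x0, B = 199, seed = 5),
    bootstrap_ci(x0, B = 199, seed = 5)
  )
  # Bernoulli(0.5) scores: percentile CI width ~ normal approximation
  withr::with_seed(10, {
    x <- as.numeric(runif(1000) < 0.5)
  })
  ci <- bootstrap_ci(x, B = 999, seed = 3)
  width <- ci$upper - ci$lower
  normal_width <- 2 * 1.96 * sqrt(0.25 / 1000)
  expect_lt(abs(width - normal_width) / normal_width, 0.2)
})

test_that("evaluate_predictions assembles a coherent report with tidiers", {
  corp <- generate_corpus(corpus_params(n = 300, seed = 20))
  be <- mock_backend(responder_params(seed = 22))
  ev <- evaluate_responses(corp, prompt_spec("ZS"), be, n_boot = 99)
  g <- glance(ev)
  expect_equal(g$n, 300)
  expect_true(g$f1_lower <= g$f1 && g$f1 <= g$f1_upper)
  expect_true(all(c(g$f1, g$accuracy, g$brier, g$mean_confidence) >= 0))
  expect_true(all(c(g$f1, g$accuracy, g$brier, g$mean_confidence) <= 1))
  td <- tidy(ev)
  expect_equal(nrow(td), 7)
  expect_equal(sum(td$support), 300)
  expect_s3_class(ggplot2::autoplot(ev), "ggplot")
})
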