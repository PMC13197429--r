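# lightweight score table for driver-level tests: Bernoulli correctness with
# an accuracy profile over word counts, bypassing the response pipeline
simulate_scores <- function(n, acc_fn, seed) {
  withr::with_seed(seed, {
    wc <- 1L + rnbinom(n, size = 2, mu = 11)
    acc <- acc_fn(wc)
    tibble::tibble(word_count = wc, correct = runif(n) < acc)
  })
}

test_that("surrogate construction preserves bin sizes exactly", {
  preds <- simulate_scores(600, function(wc) rep(0.6, length(wc)), seed = 1)
  la <- length_analysis(preds, n_shuffle = 5, seed = 2)
  expect_equal(sum(la$levels$n), 600)
  sur <- la$meta$surrogate_means
  expect_equal(dim(sur), c(6, 5))
  # reproducible surrogate draw for a fixed seed
  la2 <- length_analysis(preds, n_shuffle = 5, seed = 2)
  expect_identical(la$meta$surrogate_means, la2$meta$surrogate_means)
  expect_identical(la$tests, la2$tests)
})

test_that("a planted U-shaped length effect is recovered and significant", {
  u_profile <- function(bin) ifelse(bin <= 2, 0.8, ifelse(bin <= 4, 0.4, 0.8))
  wc0 <- withr::with_seed(3, 1L + rnbinom(1269, size = 2, mu = 11))
  edges <- length_bin_edges(wc0)
  preds <- withr::with_seed(4, {
    bin <- assign_length_bin(wc0, edges)
    tibble::tibble(word_count = wc0, correct = runif(1269) < u_profile(bin))
  })
  la <- length_analysis(preds, edges = edges, n_shuffle = 100, seed = 5)
  sc <- la$levels$score
  expect_gt(min(sc[c(1, 2, 5, 6)]), max(sc[3:4])) # U-shape in the bin means
  expect_lt(la$tests$kruskal_p, 0.001)
  expect_lt(la$tests$ks_p, 0.05)
  expect_equal(la$levels$delta, sc - sc[1])
})

test_that("a persona-blind responder yields zero deltas, in the given order", {
  corp <- generate_corpus(corpus_params(n = 200, seed = 6))
  sweep <- persona_sweep(corp, backend = mock_backend(responder_params(seed = 7)))
  expect_equal(sweep$levels$level, soz_personas())
  expect_equal(sweep$levels$delta_f1, rep(0, 4))
  expect_equal(sweep$levels$delta_accuracy, rep(0, 4))
  expect_equal(sweep$levels$delta_confidence, rep(0, 4))
  expect_error(persona_sweep(corp, personas = character(0)), "empty")
})

test_that("a planted persona effect is recovered within sampling error", {
  corp <- generate_corpus(corpus_params(n = 1269, seed = 8))
  planted <- responder_params(
    mode = "fixed", accuracy = 0.5, seed = 9,
    effect = function(entry, spec) {
      if (spec$persona == "expert epileptologist") 0.1 else 0
    }
  )
  sweep <- persona_sweep(corp, backend = mock_backend(planted))
  deltas <- sweep$levels$delta_accuracy
  expect_equal(deltas[2:3], c(0, 0)) # untouched personas stay at baseline
  expect_lt(abs(deltas[4] - 0.1), 0.03) # ~3 SE of the paired difference
  expect_gt(sweep$levels$delta_f1[4], 0.05)
})

test_that("language conditions are labeled and a blind responder shows no deltas", {
  corp <- generate_corpus(corpus_params(n = 150, seed = 10))
  translations <- tidyr::expand_grid(id = corp$id, language = c("fr", "es"))
  translations$text <- corp$text[match(translations$id, corp$id)]
  sweep <- language_sweep(corp, translations,
    languages = c("fr", "es"),
    backend = mock_backend(responder_params(seed = 11))
  )
  expect_equal(
    sweep$levels$condition,
    c("baseline", rep(c("cross", "same"), 2))
  )
  expect_equal(sweep$levels$language, c("en", "fr", "fr", "es", "es"))
  expect_equal(sweep$levels$delta_accuracy, rep(0, 5))
  expect_equal(sweep$levels$delta_f1, rep(0, 5))
  # missing translations are an error naming entries
  expect_error(
    language_sweep(corp, translations[-1, ], languages = "fr",
      backend = mock_backend(responder_params(seed = 11))
    ),
    "Missing fr translation"
  )
})

test_that("a planted same-language penalty is recovered", {
  corp <- generate_corpus(corpus_params(n = 1269, seed = 12))
  translations <- tibble::tibble(id = corp$id, language = "fr", text = corp$text)
  planted <- responder_params(
    mode = "fixed", accuracy = 0.6, seed = 13,
    effect = function(entry, spec) if (spec$language != "en") -0.05 else 0
  )
  sweep <- language_sweep(corp, translations,
    languages = "fr",
    backend = mock_backend(planted)
  )
  lv <- sweep$levels
  expect_equal(lv$delta_accuracy[lv$condition == "cross"], 0) # prompt stays English
  expect_lt(abs(lv$delta_accuracy[lv$condition == "same"] - (-0.05)), 0.02)
})

test_that("ablation results render and export", {
  preds <- simulate_scores(300, function(wc) rep(0.6, length(wc)), seed = 14)
  la <- length_analysis(preds, n_shuffle = 10, seed = 15)
  expect_s3_class(ggplot2::autoplot(la), "ggplot")
  expect_equal(tidy(la), la$levels)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ablation(la, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(out), 6)
  expect_true(all(c("level", "score", "kruskal_p", "ks_p") %in% names(out)))
})
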