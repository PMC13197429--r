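test_that("corpus generation is deterministic and respects its knobs", {
  p <- corpus_params(n = 120, seed = 42)
  expect_identical(generate_corpus(p), generate_corpus(p))
  # multi-label probability 0 -> all truth sets singleton
  single <- generate_corpus(corpus_params(n = 200, multilabel_prob = 0, seed = 1))
  expect_true(all(lengths(single$truth) == 1))
  # degenerate weights rejected
  expect_error(corpus_params(class_weights = rep(0, 7)), "sum")
  expect_error(corpus_params(class_weights = rep(0.5, 7)), "sum to 1")
})

test_that("majority fraction tracks the configured class weight", {
  w <- c(0.38, 0.25, rep(0.37 / 5, 5))
  corp <- generate_corpus(corpus_params(
    n = 5000, class_weights = w, multilabel_prob = 0, seed = 7
  ))
  maj <- mean(vapply(corp$truth, function(t) "Temporal Lobe" %in% t, logical(1)))
  expect_lt(abs(maj - 0.38), 0.02) # ~3 binomial standard errors
})

test_that("primary-label frequencies land within 3 standard errors of weights", {
  p <- corpus_params(n = 2000, seed = 8)
  corp <- generate_corpus(p)
  primary <- vapply(corp$truth, `[`, character(1), 1)
  freq <- table(factor(primary, levels = soz_regions())) / nrow(corp)
  se <- sqrt(p$class_weights * (1 - p$class_weights) / nrow(corp))
  expect_true(all(abs(as.numeric(freq) - p$class_weights) <= 3 * se + 1e-12))
})

test_that("the default synthetic corpus emulates the study composition", {
  corp <- generate_corpus(corpus_params(seed = 3))
  expect_equal(nrow(corp), 1269)
  primary <- vapply(corp$truth, `[`, character(1), 1)
  maj <- mean(primary == "Temporal Lobe")
  se <- sqrt(0.3821 * (1 - 0.3821) / 1269)
  expect_lt(abs(maj - 0.3821), 3 * se)
  expect_true(any(lengths(corp$truth) > 1)) # multi-label entries present
  expect_true(all(corp$word_count >= 1))
})

test_that("simulated responses are deterministic and well-formed", {
  corp <- generate_corpus(corpus_params(n = 20, seed = 1))
  pr <- responder_params(seed = 10)
  spec <- prompt_spec("ZS")
  r1 <- simulate_response(corp[3, ], spec, pr, 2)
  r2 <- simulate_response(corp[3, ], spec, pr, 2)
  expect_identical(r1, r2)
  expect_false(identical(r1, simulate_response(corp[3, ], spec, pr, 3)))
  expect_false(identical(r1, simulate_response(corp[4, ], spec, pr, 2)))
  # malform_rate = 0 -> every response parses cleanly with 7 keys
  for (i in 1:20) {
    parsed <- parse_response(simulate_response(corp[i, ], spec, pr, 1))
    expect_identical(parsed$status, "ok")
    expect_length(parsed$likelihoods, 7)
  }
  # chain-of-thought responses carry Reasoning and Sources
  cot <- parse_response(simulate_response(corp[1, ], prompt_spec("CoT"), pr, 1))
  expect_false(is.na(cot$reasoning))
  expect_gt(length(cot$sources), 0)
})

test_that("fixed-accuracy responder recovers its accuracy parameter", {
  corp <- generate_corpus(corpus_params(n = 3000, multilabel_prob = 0, seed = 2))
  be <- mock_backend(responder_params(mode = "fixed", accuracy = 0.6, seed = 21))
  preds <- make_predictions(
    parse_responses(collect_responses(corp, prompt_spec("ZS"), be)), corp
  )
  se <- sqrt(0.6 * 0.4 / nrow(corp))
  expect_lt(abs(mean(preds$correct) - 0.6), 3 * se)
})

test_that("malformation rate is recovered as the non-ok parse fraction", {
  corp <- generate_corpus(corpus_params(n = 5000, seed = 3))
  be <- mock_backend(responder_params(malform_rate = 0.1, seed = 31))
  parsed <- parse_responses(collect_responses(corp, prompt_spec("ZS"), be))
  frac <- mean(parsed$status != "ok")
  expect_lt(abs(frac - 0.10), 0.013)
  # defect records cover both structural breakage and value-level defects
  defects <- unlist(parsed$defects[parsed$status != "ok"])
  expect_gt(sum(grepl("malformed JSON|no JSON", defects)), 0) # broken JSON
  expect_gt(sum(grepl("assigned", defects)), 0) # None / non-numeric / missing
  expect_gt(sum(parsed$status == "partial"), 0)
})

test_that("the backend registry and response cache honour their contracts", {
  expect_error(get_backend("no-such-backend"), "No backend registered")
  be <- mock_backend(responder_params(seed = 5))
  register_backend(be)
  expect_identical(get_backend("mock")$name, "mock")

  corp <- generate_corpus(corpus_params(n = 3, seed = 4))
  spec <- prompt_spec("SC")
  cache <- withr::local_tempfile(fileext = ".jsonl")
  for (chain in 1:5) {
    backend_query(be, corp[1, ], spec, chain_index = chain, cache = cache)
  }
  recs <- read_response_cache(cache)
  expect_equal(nrow(recs), 5)
  expect_equal(recs$chain_index, 1:5)
  expect_equal(unique(recs$entry_id), corp$id[1])
  expect_equal(unique(recs$backend), "mock")
  # identical prompt + seed + chain -> identical cached text
  expect_identical(
    backend_query(be, corp[1, ], spec, chain_index = 1),
    recs$raw_text[1]
  )
})
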