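write_toy_tsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("id\ttext\tlanguage\tregions", rows), path)
  path
}

test_that("a valid delimited corpus loads with preprocessed text", {
  path <- write_toy_tsv(c(
    "a1\tLOC with automatisms\ten\tTemporal Lobe",
    "a2\tversive head turning\ten\tFrontal Lobe;Parietal Lobe",
    "a3\tvisual aura\ten\tOccipital Lobe"
  ))
  corp <- read_corpus(path)
  expect_equal(nrow(corp), 3)
  expect_equal(corp$text[1], "loss of consciousness with automatisms")
  expect_equal(corp$truth[[2]], c("Frontal Lobe", "Parietal Lobe"))
  expect_equal(corp$word_count, count_words(corp$text))
})

test_that("unknown region names and empty files are rejected with location", {
  bad <- write_toy_tsv(c(
    "a1\tsome text\ten\tTemporal Lobe",
    "a2\tother text\ten\tTempral Lobe"
  ))
  expect_error(read_corpus(bad), "row 2.*Tempral Lobe")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\ttext\tlanguage\tregions", empty)
  expect_error(read_corpus(empty), "empty")
  noregion <- write_toy_tsv("a1\tsome text\ten\t")
  expect_error(read_corpus(noregion), "empty ground-truth")
})

test_that("preprocessing expands, corrects, strips, and is idempotent", {
  rules <- preprocess_rules(
    abbreviations = c(LOC = "loss of consciousness"),
    spellings = c(siezure = "seizure"),
    stop_terms = c("patient", "reported")
  )
  expect_equal(
    preprocess_text("patient reported LOC during siezure", rules),
    "loss of consciousness during seizure"
  )
  expect_equal(preprocess_text("patient reported", rules), "")
  expect_equal(preprocess_text("", rules), "")
  # idempotence over generated strings mixing rule keys, outputs, and noise
  vocab <- c(
    "LOC", "siezure", "patient", "reported", "loss", "of", "consciousness",
    "aura", "rising", "automatisms", "w/", "head"
  )
  withr::with_seed(99, {
    for (i in 1:100) {
      x <- paste(sample(vocab, sample(0:12, 1), replace = TRUE), collapse = " ")
      once <- preprocess_text(x, rules)
      expect_identical(preprocess_text(once, rules), once)
    }
  })
  # shipped default rules are idempotent too
  defaults <- preprocess_rules()
  samples <- c("LOC w/ GTC siezure", "patient reportedly had dejavu", "R UL jerking")
  for (x in samples) {
    once <- preprocess_text(x, defaults)
    expect_identical(preprocess_text(once, defaults), once)
  }
})

test_that("length bins are half-open and match a brute-force histogram", {
  edges <- c(1, 4, 8, 15, 25, 40, 61)
  # left edge inclusive, right edge exclusive
  expect_equal(assign_length_bin(4, edges), 2)
  expect_equal(assign_length_bin(c(1, 3), edges), c(1, 1))
  expect_equal(assign_length_bin(40, edges), 6) # right edge of bin 5 -> bin 6
  expect_error(assign_length_bin(61, edges), "outside")
  expect_error(assign_length_bin(0, edges), "outside")

  counts <- rep(1:60, each = 2)
  dec_edges <- length_bin_edges(counts, n_bins = 6)
  bins <- assign_length_bin(counts, dec_edges)
  brute <- vapply(seq_len(length(dec_edges) - 1), function(m) {
    sum(counts >= dec_edges[m] & counts < dec_edges[m + 1])
  }, numeric(1))
  expect_equal(as.integer(tabulate(bins, length(dec_edges) - 1)), as.integer(brute))
  expect_equal(sum(brute), length(counts))
  expect_match(bin_labels(edges)[1], "^\\[1, 4\\)$")
})

test_that("the naive baseline is the majority inclusion fraction", {
  corp <- toy_corpus(c(
    rep(list("Temporal Lobe"), 6),
    rep(list("Frontal Lobe"), 4)
  ))
  nb <- naive_baseline(corp)
  expect_equal(nb$region, "Temporal Lobe")
  expect_equal(nb$accuracy, 0.6)
  # all entries share a truth region -> a perfect constant predictor
  one <- toy_corpus(rep(list("Insula"), 5))
  expect_equal(naive_baseline(one)$accuracy, 1.0)
  expect_equal(naive_baseline(one)$weighted_f1, 1.0)
  # invariant under shuffling
  withr::with_seed(4, {
    shuffled <- corp[sample(nrow(corp)), ]
  })
  expect_equal(naive_baseline(shuffled), nb)
  # a multi-label truth counts the majority region when it is included
  multi <- toy_corpus(list(
    c("Frontal Lobe", "Temporal Lobe"), "Temporal Lobe", "Frontal Lobe"
  ))
  expect_equal(naive_baseline(multi)$accuracy, 2 / 3)
})

test_that("corpus round trip through the TSV dialect is stable", {
  corp <- generate_corpus(corpus_params(n = 40, seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corp, path)
  back <- read_corpus(path, rules = NULL)
  expect_equal(back$id, corp$id)
  expect_equal(back$text, corp$text)
  expect_equal(back$truth, corp$truth)
  expect_equal(back$word_count, corp$word_count)
})

test_that("corpus summary counts entries, classes, and lengths", {
  corp <- generate_corpus(corpus_params(n = 200, seed = 6))
  s <- summarize_corpus(corp)
  expect_equal(s$n_entries, 200)
  expect_equal(sum(unlist(s$length_bins)), 200)
  expect_gte(sum(unlist(s$region_counts)), 200) # multi-label inflates counts
})
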