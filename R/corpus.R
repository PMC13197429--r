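#' Read a semiology corpus from a delimited file
#'
#' A corpus is a tab-separated UTF-8 table with a header row and columns
#' `id`, `text`, `language`, `regions`, where `regions` holds one or more
#' canonical region names joined by `";"` (tabs are used because free-text
#' descriptions routinely contain commas). Texts are normalized with
#' [preprocess_text()] on load and word counts recomputed from the
#' normalized text.
#'
#' @param path Path to the TSV file.
#' @param rules Preprocessing rules, see [preprocess_rules()].
#' @return A corpus tibble with columns `id` (character), `text`,
#'   `language`, `truth` (list-column of character vectors, each a nonempty
#'   subset of [soz_regions()]) and `word_count`.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "id\ttext\tlanguage\tregions",
#'   "e1\tepigastric aura rising to throat\ten\tTemporal Lobe",
#'   "e2\tversive head turning\ten\tFrontal Lobe;Parietal Lobe"
#' ), tsv)
#' read_corpus(tsv)
#' @export
read_corpus <- function(path, rules = preprocess_rules()) {
  if (!file.exists(path)) abort(sprintf("Corpus file not found: %s", path))
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) == 0) abort(sprintf("Corpus file is empty: %s", path))
  needed <- c("id", "text", "language", "regions")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(sprintf("Corpus is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  df$regions[is.na(df$regions)] <- ""
  truth <- map2(strsplit(df$regions, ";", fixed = TRUE), seq_len(nrow(df)),
    function(rs, i) {
      rs <- trimws(rs)
      rs <- rs[!is.na(rs) & nzchar(rs)]
      if (length(rs) == 0) {
        abort(sprintf("Row %d has an empty ground-truth region set.", i))
      }
      unique(match_regions(rs, row = i))
    }
  )
  as_corpus(tibble(
    id = df$id,
    text = df$text,
    language = df$language %||% "en",
    truth = truth
  ), rules = rules)
}

#' Validate (and normalize) a corpus tibble
#'
#' Checks the corpus contract — character `id` (unique), `text`, `language`,
#' and a `truth` list-column of nonempty subsets of [soz_regions()] —
#' preprocesses the text, and (re)derives `word_count`.
#'
#' @param x A data frame with columns `id`, `text`, `language`, `truth`.
#' @param rules Preprocessing rules applied to `text`; `NULL` to keep text
#'   as-is (word counts are still recomputed).
#' @return A validated corpus tibble.
#' @export
as_corpus <- function(x, rules = preprocess_rules()) {
  x <- as_tibble(x)
  needed <- c("id", "text", "language", "truth")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort(sprintf("Corpus is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("Corpus has no entries.")
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id)) abort("Corpus entry ids must be unique.")
  x$truth <- imap(x$truth, function(rs, i) {
    if (length(rs) == 0) abort(sprintf("Row %d has an empty ground-truth region set.", i))
    unique(match_regions(rs, row = i))
  })
  if (!is.null(rules)) x$text <- preprocess_text(x$text, rules)
  x$word_count <- count_words(x$text)
  x[, unique(c(needed, "word_count", names(x)))]
}

#' Write a corpus to the package's TSV dialect
#'
#' @param corpus A corpus tibble (see [read_corpus()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  df <- tibble(
    id = corpus$id, text = corpus$text, language = corpus$language,
    regions = map_chr(corpus$truth, paste, collapse = ";")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Summarize a corpus
#'
#' @param corpus A corpus tibble.
#' @param edges Optional length-bin edges for the histogram; defaults to
#'   [length_bin_edges()] of the corpus.
#' @return A list (JSON-ready): `n_entries`, per-region inclusion counts,
#'   multi-label fraction, and a word-count histogram over the length bins.
#' @export
summarize_corpus <- function(corpus, edges = NULL) {
  counts <- region_counts(corpus)
  edges <- edges %||% length_bin_edges(corpus$word_count)
  bins <- assign_length_bin(corpus$word_count, edges)
  hist <- as.integer(tabulate(bins, nbins = length(edges) - 1L))
  list(
    n_entries = nrow(corpus),
    region_counts = as.list(counts),
    multilabel_fraction = mean(lengths(corpus$truth) > 1),
    length_bins = setNames(as.list(hist), bin_labels(edges)),
    mean_word_count = mean(corpus$word_count)
  )
}

# per-region inclusion counts (an entry with k truth regions counts once for
# each), in canonical order
region_counts <- function(corpus) {
  all_regions <- unlist(corpus$truth)
  counts <- table(factor(all_regions, levels = soz_regions()))
  setNames(as.integer(counts), soz_regions())
}

#' Naive majority-class baseline
#'
#' The chance-level reference is a constant classifier that always predicts
#' the region most frequently present in the ground truth. A prediction is
#' correct when it lies in an entry's (possibly multi-label) truth set, so
#' the baseline accuracy is the inclusion fraction of the majority region.
#' The weighted F1 of the same constant predictor is also reported.
#'
#' @param corpus A corpus tibble.
#' @return One-row tibble: `region` (majority region), `n`, `accuracy`,
#'   `weighted_f1`.
#' @examples
#' corp <- generate_corpus(corpus_params(n = 200, seed = 1))
#' naive_baseline(corp)
#' @export
naive_baseline <- function(corpus) {
  stopifnot(nrow(corpus) >= 1)
  counts <- region_counts(corpus)
  majority <- soz_regions()[which.max(counts)] # ties: canonical order
  correct <- map_lgl(corpus$truth, function(t) majority %in% t)
  preds <- tibble(
    id = corpus$id,
    predicted = majority,
    truth = corpus$truth,
    correct = correct,
    p_pred = 1,
    confidence = 1
  )
  f1 <- weighted_prf1(preds)$f1
  tibble(
    region = majority, n = nrow(corpus),
    accuracy = mean(correct), weighted_f1 = f1
  )
}

#' Length-bin edges from corpus quantiles
#'
#' Default edges split the observed word counts into `n_bins` roughly
#' equally populated half-open bins. Edges are integers; the last edge is
#' one past the maximum so every observed count is covered.
#'
#' @param word_count Integer vector of word counts.
#' @param n_bins Number of bins (default 6).
#' @return Integer vector of `n_bins + 1` strictly increasing edges.
#' @export
length_bin_edges <- function(word_count, n_bins = 6) {
  stopifnot(n_bins >= 1, length(word_count) >= 1)
  probs <- seq(0, 1, length.out = n_bins + 1)
  edges <- unname(quantile(word_count, probs, type = 1))
  edges <- floor(edges)
  edges[length(edges)] <- max(word_count) + 1L
  edges <- unique(as.integer(edges))
  if (length(edges) < n_bins + 1) {
    # heavily tied counts: fall back to an even split of the range
    rng <- range(word_count)
    edges <- unique(as.integer(round(seq(rng[1], rng[2] + 1, length.out = n_bins + 1))))
  }
  if (length(edges) < 2) abort("Cannot construct length bins: degenerate word counts.")
  edges
}

#' Assign word counts to half-open length bins
#'
#' Bin `m` covers `[edges[m], edges[m+1])` — each range includes its left
#' edge and excludes its right edge.
#'
#' @param word_count Integer vector.
#' @param edges Ascending integer edges (length = bins + 1).
#' @return Integer vector of bin indices in `1:(length(edges) - 1)`.
#' @export
assign_length_bin <- function(word_count, edges) {
  edges <- as.numeric(edges)
  if (is.unsorted(edges, strictly = TRUE)) abort("Bin edges must be strictly increasing.")
  out_of_range <- word_count < edges[1] | word_count >= edges[length(edges)]
  if (any(out_of_range)) {
    abort(sprintf(
      "Word count(s) outside the binned range [%s, %s): %s",
      edges[1], edges[length(edges)],
      paste(unique(word_count[out_of_range]), collapse = ", ")
    ))
  }
  findInterval(word_count, edges, rightmost.closed = FALSE, left.open = FALSE)
}

#' Half-open labels for length bins
#' @param edges Ascending edges.
#' @return Character vector like `"[1, 5)"`.
#' @export
bin_labels <- function(edges) {
  sprintf("[%s, %s)", head(edges, -1), edges[-1])
}
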