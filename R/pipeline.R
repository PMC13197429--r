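#' Collect raw responses for a corpus under one prompt specification
#'
#' Queries the backend once per entry and chain (self-consistency uses 5
#' chains). For few-shot strategies, exemplars are selected per entry with
#' the query entry excluded (leakage guard). All queries are appended to
#' the JSONL cache when one is given.
#'
#' @param corpus A corpus tibble.
#' @param spec A [prompt_spec()].
#' @param backend A `soz_backend` or registered backend name.
#' @param cache Optional JSONL cache path.
#' @param exemplar_seed Seed for per-entry exemplar selection.
#' @return Responses tibble: `entry_id`, `strategy`, `persona`, `language`,
#'   `chain_index`, `raw_text`.
#' @export
collect_responses <- function(corpus, spec, backend = mock_backend(),
                              cache = NULL, exemplar_seed = 1L) {
  backend <- get_backend(backend)
  n_rows <- nrow(corpus) * spec$n_chains
  entry_id <- character(n_rows)
  chain_id <- integer(n_rows)
  raw_text <- character(n_rows)
  k <- 0L
  for (i in seq_len(nrow(corpus))) {
    entry <- corpus[i, ]
    entry_spec <- spec
    if (is_fs(spec$strategy) && is.null(spec$exemplars)) {
      entry_spec$exemplars <- select_exemplars(
        corpus,
        k = spec$k, seed = exemplar_seed, exclude = entry$id,
        reasoning = spec$strategy == "FS-CoT", language = spec$language
      )
    }
    for (chain in seq_len(spec$n_chains)) {
      raw <- backend_query(backend, entry, entry_spec, chain_index = chain, cache = cache)
      k <- k + 1L
      entry_id[k] <- entry$id
      chain_id[k] <- chain
      raw_text[k] <- raw
    }
  }
  tibble(
    entry_id = entry_id, strategy = spec$strategy, persona = spec$persona,
    language = spec$language, chain_index = chain_id, raw_text = raw_text
  )
}

#' Aggregate self-consistency chains by median voting
#'
#' Groups a parsed-response table by entry, checks the 5-chain contract,
#' and reduces each group to the [median_vote()] winner. Failed chains
#' participate as the all-zero vectors the parser produced for them.
#'
#' @param parsed Parsed responses ([parse_responses()]) with 5 chains per
#'   entry.
#' @return Parsed-style tibble with one row per entry; `chain_index` is
#'   the winning chain, and `n_failed_chains` counts failed chains.
#' @export
vote_chains <- function(parsed) {
  split_idx <- split(seq_len(nrow(parsed)), parsed$entry_id)
  rows <- map(split_idx, function(ix) {
    sub <- parsed[ix, ]
    sub <- sub[order(sub$chain_index), ]
    if (nrow(sub) != 5) {
      abort(sprintf(
        "Entry %s has %d chains; self-consistency requires exactly 5.",
        sub$entry_id[1], nrow(sub)
      ))
    }
    vote <- median_vote(sub$likelihoods)
    w <- vote$winner
    tibble(
      entry_id = sub$entry_id[1],
      chain_index = sub$chain_index[w],
      likelihoods = list(vote$likelihoods),
      status = sub$status[w],
      defects = sub$defects[w],
      reasoning = sub$reasoning[w],
      n_failed_chains = sum(sub$status == "failed")
    )
  })
  out <- bind_rows(rows)
  out[match(unique(parsed$entry_id), out$entry_id), ]
}

#' Run the full scoring pipeline for one condition
#'
#' Collect (or replay), parse, aggregate self-consistency chains, and
#' score one corpus under one prompt specification: the single scoring
#' path shared by the evaluation grid and all ablation drivers.
#'
#' @inheritParams collect_responses
#' @param responses Optional pre-collected responses tibble (cache
#'   replay); when given the backend is not queried.
#' @param lexicon A [region_lexicon()].
#' @param prob Probability pairing for calibration (see
#'   [make_predictions()]).
#' @param bins,n_boot,level,seed Passed to [evaluate_predictions()].
#' @return A `soz_eval` object; its `predictions` carry per-entry detail.
#' @export
evaluate_responses <- function(corpus, spec = prompt_spec("ZS"),
                               backend = mock_backend(), responses = NULL,
                               cache = NULL, lexicon = default_lexicon(),
                               prob = "predicted", bins = 10L,
                               n_boot = 999L, level = 0.95, seed = 1L,
                               exemplar_seed = 1L) {
  responses <- responses %||%
    collect_responses(corpus, spec, backend, cache = cache, exemplar_seed = exemplar_seed)
  parsed <- parse_responses(responses, lexicon = lexicon)
  if (spec$strategy == "SC") parsed <- vote_chains(parsed)
  preds <- make_predictions(parsed, corpus, prob = prob)
  evaluate_predictions(preds, bins = bins, n_boot = n_boot, level = level, seed = seed)
}
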