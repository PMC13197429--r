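soz_strategies <- function() c("ZS", "FS", "CoT", "FS-CoT", "SC")

#' Built-in persona sweep
#'
#' The persona prefix ranges from a generic assistant to an increasingly
#' specialized clinical role; the first element is the baseline the persona
#' ablation compares against.
#' @return Character vector of personas.
#' @export
soz_personas <- function() {
  c("AI assistant", "medical assistant", "neurologist", "expert epileptologist")
}

is_cot <- function(strategy) strategy %in% c("CoT", "FS-CoT", "SC")
is_fs <- function(strategy) strategy %in% c("FS", "FS-CoT")

#' Specify a prompt
#'
#' A prompt specification bundles the persona `P`, instruction `I`, query
#' template `Q`, strategy, language(s), and few-shot exemplars. Strategies:
#' `"ZS"` (zero-shot), `"FS"` (few-shot, K exemplars), `"CoT"`
#' (chain-of-thought), `"FS-CoT"` (few-shot chain-of-thought), `"SC"`
#' (self-consistency: a chain-of-thought prompt answered by 5 independent
#' chains).
#'
#' `query_language` covers the cross-language condition, where only the
#' semiology description is in a different language while the surrounding
#' prompt stays in `language`; by default both are the same.
#'
#' @param strategy One of `"ZS"`, `"FS"`, `"CoT"`, `"FS-CoT"`, `"SC"`.
#' @param persona Persona text inserted into the literal prefix
#'   `"you are a {persona}"` (template preserved verbatim, including the
#'   article).
#' @param language ISO code of the prompt language (instruction and region
#'   names); must be covered by the shipped prompt resources
#'   (en, fr, es, zh).
#' @param query_language ISO code of the semiology-description language.
#' @param k Number of few-shot exemplars (K; default 5). Ignored for
#'   non-few-shot strategies, which carry no exemplars.
#' @param exemplars Exemplar tibble from [select_exemplars()]; required at
#'   [build_prompt()] time for `"FS"`/`"FS-CoT"`.
#' @param n_chains Number of response chains; forced to 5 for `"SC"`.
#' @return A `soz_prompt_spec` list.
#' @export
prompt_spec <- function(strategy = c("ZS", "FS", "CoT", "FS-CoT", "SC"),
                        persona = "AI assistant",
                        language = "en",
                        query_language = language,
                        k = 5L,
                        exemplars = NULL,
                        n_chains = NULL) {
  strategy <- match.arg(strategy)
  if (is_fs(strategy)) {
    if (k < 1) abort("Few-shot strategies require k >= 1 exemplars.")
  } else {
    k <- 0L
    if (!is.null(exemplars) && nrow(exemplars) > 0) {
      abort(sprintf("Strategy %s takes no exemplars.", strategy))
    }
    exemplars <- NULL
  }
  n_chains <- if (strategy == "SC") 5L else as.integer(n_chains %||% 1L)
  structure(list(
    strategy = strategy, persona = persona, language = language,
    query_language = query_language, k = as.integer(k),
    exemplars = exemplars, n_chains = n_chains
  ), class = "soz_prompt_spec")
}

#' @export
print.soz_prompt_spec <- function(x, ...) {
  cat(sprintf(
    "<soz_prompt_spec> %s | persona: %s | language: %s%s | chains: %d%s\n",
    x$strategy, x$persona, x$language,
    if (!identical(x$query_language, x$language)) paste0(" (query: ", x$query_language, ")") else "",
    x$n_chains,
    if (is_fs(x$strategy)) sprintf(" | K=%d", x$k) else ""
  ))
  invisible(x)
}

prompt_resource <- function(stem, language) {
  path <- system.file("extdata", "prompts", sprintf("%s_%s.txt", stem, language),
    package = "sozloc"
  )
  if (!nzchar(path)) {
    abort(sprintf(
      "No %s prompt resource for language %s; shipped languages are en, fr, es, zh.",
      stem, sQuote(language)
    ))
  }
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = " ")
}

instruction_text <- function(language) {
  surfaces <- region_surface(language)
  tmpl <- prompt_resource("instruction", language)
  sub("{regions}", paste(sprintf('"%s"', surfaces), collapse = ", "), tmpl, fixed = TRUE)
}

fscot_reasoning_pool <- function() {
  path <- system.file("extdata", "prompts", "fscot_reasoning_en.txt", package = "sozloc")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Select few-shot exemplars from a corpus
#'
#' Exemplars are sampled uniformly without replacement, stratified across
#' distinct primary truth regions when feasible, never including the
#' excluded (query) entry. Each exemplar's target output is a serialized
#' likelihood dictionary that concentrates 90% of its mass evenly on the
#' entry's truth region(s); with `reasoning = TRUE` an expert-reasoning
#' text from the packaged pool (placeholders, see
#' `inst/extdata/prompts/fscot_reasoning_en.txt`) is attached for few-shot
#' chain-of-thought.
#'
#' @param corpus A corpus tibble.
#' @param k Number of exemplars; must be smaller than the corpus size.
#' @param seed Integer seed (selection is deterministic given it).
#' @param exclude Entry id(s) to never sample (leakage guard).
#' @param reasoning Attach expert-reasoning text (for `"FS-CoT"`).
#' @param language Language for the serialized exemplar outputs.
#' @return Tibble: `id`, `text`, `output`.
#' @export
select_exemplars <- function(corpus, k = 5L, seed = 1L, exclude = NULL,
                             reasoning = FALSE, language = "en") {
  pool <- corpus[!corpus$id %in% exclude, ]
  if (k >= nrow(corpus) || k > nrow(pool)) {
    abort(sprintf("Cannot select %d exemplars from a corpus of %d entries.", k, nrow(corpus)))
  }
  withr::with_seed(seed, {
    primary <- map_chr(pool$truth, 1)
    # stratified first pass: one draw per region class, then fill uniformly
    picks <- integer()
    for (r in sample(unique(primary))) {
      if (length(picks) >= k) break
      cand <- setdiff(which(primary == r), picks)
      if (length(cand)) picks <- c(picks, cand[sample.int(length(cand), 1)])
    }
    if (length(picks) < k) {
      rest <- setdiff(seq_len(nrow(pool)), picks)
      picks <- c(picks, rest[sample.int(length(rest), k - length(picks))])
    }
    picks <- picks[seq_len(k)]
    chosen <- pool[picks, ]
    pool_text <- if (reasoning) fscot_reasoning_pool() else NULL
    output <- imap(chosen$truth, function(truth, i) {
      serialize_likelihoods(
        exemplar_likelihoods(truth),
        language = language,
        reasoning = if (reasoning) pool_text[((i - 1) %% length(pool_text)) + 1],
        sources = if (reasoning) "[PLACEHOLDER exemplar source]"
      )
    })
    tibble(id = chosen$id, text = chosen$text, output = unlist(output))
  })
}

# 90% of the mass split evenly over the truth regions, 10% over the rest
exemplar_likelihoods <- function(truth) {
  values <- setNames(numeric(7), soz_regions())
  values[truth] <- 90 / length(truth)
  rest <- setdiff(soz_regions(), truth)
  values[rest] <- 10 / length(rest)
  values
}

#' Build the full prompt text for one entry
#'
#' Assembles, in order: the persona prefix (`"you are a {persona}"`
#' verbatim), the instruction requiring the JSON output format over the
#' seven regions, the chain-of-thought sentence (`"Solve the problem in
#' step by step manner"`) with the required `Reasoning`/`Sources` keys for
#' chain-of-thought strategies, the exemplar blocks for few-shot
#' strategies, and the query text. A pure function of `(entry, spec)`.
#'
#' @param entry One corpus row; `entry$text` is used as the query. For
#'   cross-/same-language conditions pass the translated text in the entry.
#' @param spec A [prompt_spec()]. Few-shot specs must carry exemplars
#'   disjoint from the query entry (leakage guard: overlap is an error).
#' @return A single prompt string.
#' @examples
#' corp <- generate_corpus(corpus_params(n = 20, seed = 1))
#' spec <- prompt_spec("CoT", persona = "expert epileptologist")
#' cat(substr(build_prompt(corp[1, ], spec), 1, 80))
#' @export
build_prompt <- function(entry, spec) {
  stopifnot(inherits(spec, "soz_prompt_spec"))
  parts <- sprintf("you are a %s.", spec$persona)
  parts <- c(parts, instruction_text(spec$language))
  if (is_cot(spec$strategy)) {
    parts <- c(parts, prompt_resource("cot", spec$language))
  }
  if (is_fs(spec$strategy)) {
    ex <- spec$exemplars
    if (is.null(ex) || nrow(ex) < 1) {
      abort(sprintf("Strategy %s requires exemplars; see select_exemplars().", spec$strategy))
    }
    if (any(ex$id %in% entry$id)) {
      abort("Exemplar overlaps the query entry (leakage guard).")
    }
    blocks <- sprintf("Semiology: \"%s\"\nOutput: %s", ex$text, ex$output)
    parts <- c(parts, "Examples:", blocks)
  }
  parts <- c(parts, sprintf("Semiology: \"%s\"\nOutput:", entry$text[[1]]))
  paste(parts, collapse = "\n\n")
}
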