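#' Parameters for the synthetic semiology corpus
#'
#' The generator emulates the structural features of a curated semiology
#' corpus: class-imbalanced multi-label ground truth over the seven regions,
#' variable description lengths, and a language mix. Defaults mirror the
#' study corpus this harness targets: 1,269 entries with the temporal lobe
#' as the majority class at a 0.3821 share of primary labels.
#'
#' @param n Number of entries (default 1269).
#' @param class_weights Named or unnamed 7-vector of primary-label
#'   probabilities in canonical region order; must sum to 1. The default is
#'   a temporal-dominant imbalance profile (0.3821 temporal).
#' @param multilabel_prob Probability that an entry carries a second
#'   ground-truth region (default 0.1). Additional regions are drawn in
#'   proportion to `class_weights` among the remaining regions, so region
#'   inclusion fractions slightly exceed primary-label fractions.
#' @param wc_mu,wc_size Mean and dispersion of the negative-binomial word
#'   count model (counts are `1 + NB(size, mu - 1)`, so every text has at
#'   least one word).
#' @param languages Character vector of language codes.
#' @param language_weights Mixing weights over `languages`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `soz_corpus_params` list.
#' @export
corpus_params <- function(n = 1269,
                          class_weights = default_class_weights(),
                          multilabel_prob = 0.1,
                          wc_mu = 12, wc_size = 2,
                          languages = "en",
                          language_weights = NULL,
                          seed = 1) {
  w <- as_region_vector(class_weights)
  if (any(w < 0) || sum(w) <= 0) abort("class_weights must be nonnegative with positive sum.")
  if (abs(sum(w) - 1) > 1e-8) abort("class_weights must sum to 1.")
  if (all(w == 0)) abort("class_weights are degenerate (all zero).")
  stopifnot(n >= 1, multilabel_prob >= 0, multilabel_prob <= 1, wc_mu > 1, wc_size > 0)
  language_weights <- language_weights %||% rep(1 / length(languages), length(languages))
  stopifnot(length(language_weights) == length(languages))
  structure(list(
    n = as.integer(n), class_weights = w, multilabel_prob = multilabel_prob,
    wc_mu = wc_mu, wc_size = wc_size, languages = languages,
    language_weights = language_weights / sum(language_weights),
    seed = as.integer(seed)
  ), class = "soz_corpus_params")
}

#' Default class imbalance profile
#'
#' Temporal-lobe share fixed at 0.3821 (the majority-class share of the
#' study corpus); the remaining mass follows the clinical prevalence
#' ordering (frontal next, hypothalamic semiology rare).
#'
#' @return Named numeric 7-vector summing to 1.
#' @export
default_class_weights <- function() {
  setNames(
    c(0.3821, 0.2600, 0.0600, 0.1100, 0.0800, 0.0700, 0.0379),
    soz_regions()
  )
}

# small vocabulary of semiology-flavored tokens used for synthetic texts;
# deliberately disjoint from the default preprocessing rule keys so
# preprocessing is a no-op on generated text
synthetic_vocab <- function() {
  c(
    "aura", "rising", "epigastric", "sensation", "oral", "automatism",
    "staring", "unresponsive", "head", "version", "clonic", "jerking",
    "tonic", "posturing", "hypermotor", "agitation", "fear", "visual",
    "flashing", "lights", "numbness", "tingling", "gustatory", "olfactory",
    "hallucination", "speech", "arrest", "laughing", "gelastic", "flushing",
    "sweating", "palpitations", "dystonic", "arm", "leg", "face", "eye",
    "deviation", "blinking", "chewing", "swallowing", "restlessness"
  )
}

#' Generate a synthetic semiology corpus
#'
#' Deterministic given `params$seed`. Texts are synthetic token sequences
#' (not clinically meaningful prose); ground truth, class imbalance, word
#' counts, and language mix follow `params`.
#'
#' @param params A [corpus_params()] object.
#' @return A corpus tibble (same contract as [read_corpus()]).
#' @examples
#' corp <- generate_corpus(corpus_params(n = 50, seed = 7))
#' dplyr::count(corp, lengths(truth))
#' @export
generate_corpus <- function(params = corpus_params()) {
  stopifnot(inherits(params, "soz_corpus_params"))
  regions <- soz_regions()
  w <- params$class_weights
  withr::with_seed(params$seed, {
    primary <- sample(regions, params$n, replace = TRUE, prob = w)
    extra <- runif(params$n) < params$multilabel_prob
    truth <- map2(primary, extra, function(p, e) {
      if (!e) return(p)
      others <- setdiff(regions, p)
      c(p, sample(others, 1, prob = w[others]))
    })
    wc <- 1L + rnbinom(params$n, size = params$wc_size, mu = params$wc_mu - 1)
    vocab <- synthetic_vocab()
    text <- map_chr(wc, function(k) paste(sample(vocab, k, replace = TRUE), collapse = " "))
    language <- sample(params$languages, params$n,
      replace = TRUE, prob = params$language_weights
    )
    as_corpus(tibble(
      id = sprintf("syn%05d", seq_len(params$n)),
      text = text, language = language, truth = truth
    ), rules = NULL)
  })
}
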