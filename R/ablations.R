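new_ablation <- function(axis, levels, tests = list(), baseline = NULL, meta = list()) {
  structure(
    list(axis = axis, levels = levels, tests = tests, baseline = baseline, meta = meta),
    class = "soz_ablation"
  )
}

#' @export
print.soz_ablation <- function(x, ...) {
  cat(sprintf("<soz_ablation> axis: %s\n", x$axis))
  print(x$levels)
  if (length(x$tests)) {
    cat(paste(
      map_chr(names(x$tests), function(nm) sprintf("%s = %.4g", nm, x$tests[[nm]])),
      collapse = " | "
    ), "\n")
  }
  invisible(x)
}

#' @method tidy soz_ablation
#' @export
tidy.soz_ablation <- function(x, ...) x$levels

#' Description-length analysis with a shuffled surrogate
#'
#' Bins per-entry scores into six half-open word-count ranges, reports the
#' mean score and its standard error per bin, tests for differences across
#' bins (Kruskal-Wallis), and contrasts the observed per-bin means against
#' surrogate data in which entries are reassigned to bins at random with
#' bin sizes preserved exactly (two-sample Kolmogorov-Smirnov test of the
#' observed bin means against the pooled surrogate bin means). A
#' significant KS test indicates the length profile is a genuine effect
#' rather than a sampling artifact.
#'
#' @param predictions A predictions tibble with `word_count` and `correct`
#'   (any per-entry score in a `score` column is used when present).
#' @param edges Six-bin ascending integer edges; defaults to corpus
#'   word-count quantiles via [length_bin_edges()].
#' @param n_shuffle Number of surrogate reassignments (default 100).
#' @param seed Integer seed for the surrogate draws.
#' @return A `soz_ablation` (axis `"length"`): per-bin `level`, `n`,
#'   `score`, `sem`, `delta` (vs. the first bin), plus `kruskal_p` and
#'   `ks_p` test results. Empty bins are flagged and excluded from tests.
#' @export
length_analysis <- function(predictions, edges = NULL, n_shuffle = 100L, seed = 1L) {
  stopifnot(nrow(predictions) >= 1, n_shuffle >= 1)
  score <- if ("score" %in% names(predictions)) {
    predictions$score
  } else {
    as.numeric(predictions$correct)
  }
  wc <- predictions$word_count
  edges <- edges %||% length_bin_edges(wc)
  bin <- assign_length_bin(wc, edges)
  nb <- length(edges) - 1L
  n_per <- tabulate(bin, nbins = nb)
  means <- vapply(seq_len(nb), function(m) {
    if (n_per[m] == 0) NA_real_ else mean(score[bin == m])
  }, numeric(1))
  sems <- vapply(seq_len(nb), function(m) {
    if (n_per[m] < 2) NA_real_ else sd(score[bin == m]) / sqrt(n_per[m])
  }, numeric(1))
  occupied <- n_per > 0
  if (any(!occupied)) {
    warn(sprintf(
      "Empty length bin(s) excluded from tests: %s",
      paste(bin_labels(edges)[!occupied], collapse = ", ")
    ))
  }
  kw <- kruskal.test(score[bin %in% which(occupied)], factor(bin[bin %in% which(occupied)]))
  surrogate <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffle), function(s) {
      sb <- bin[sample.int(length(bin))] # permuted labels: sizes preserved
      vapply(seq_len(nb), function(m) {
        if (n_per[m] == 0) NA_real_ else mean(score[sb == m])
      }, numeric(1))
    }, numeric(nb))
  })
  ks <- suppressWarnings(
    ks.test(means[occupied], as.vector(surrogate[occupied, , drop = FALSE]))
  )
  levels <- tibble(
    level = bin_labels(edges), n = n_per, score = means, sem = sems,
    delta = means - means[which(occupied)[1]]
  )
  new_ablation("length", levels,
    tests = list(
      kruskal_stat = unname(kw$statistic), kruskal_p = kw$p.value,
      ks_stat = unname(ks$statistic), ks_p = ks$p.value
    ),
    baseline = levels$level[which(occupied)[1]],
    meta = list(edges = edges, n_shuffle = n_shuffle, seed = seed,
                surrogate_means = surrogate)
  )
}

# shared sweep core: one scoring path for every ablation axis
sweep_condition <- function(corpus, spec, backend, lexicon, seed) {
  ev <- evaluate_responses(corpus, spec, backend,
    lexicon = lexicon, n_boot = 1L, seed = seed
  )
  tibble(
    f1 = ev$f1, accuracy = ev$accuracy,
    sd_correct = sd(as.numeric(ev$predictions$correct)),
    mean_confidence = ev$mean_confidence, n = ev$n
  )
}

#' Persona sweep (in-context impersonation)
#'
#' Evaluates the corpus zero-shot under each persona (zero-shot, so
#' few-shot exemplars cannot confound the comparison) and reports F1 and
#' mean confidence per persona with deltas against the first persona
#' (the baseline `"AI assistant"` in the default sweep).
#'
#' @param corpus A corpus tibble.
#' @param personas Ordered character vector; the first is the baseline.
#' @param backend Backend to query.
#' @param lexicon A [region_lexicon()].
#' @param seed Seed passed to the scoring path.
#' @return A `soz_ablation` (axis `"persona"`) with per-level `f1`,
#'   `accuracy`, `mean_confidence` and deltas vs. the baseline persona.
#' @export
persona_sweep <- function(corpus, personas = soz_personas(),
                          backend = mock_backend(),
                          lexicon = default_lexicon(), seed = 1L) {
  if (length(personas) == 0) abort("Persona list is empty.")
  rows <- map(personas, function(p) {
    spec <- prompt_spec("ZS", persona = p)
    sweep_condition(corpus, spec, backend, lexicon, seed)
  })
  levels <- bind_rows(rows) |>
    mutate(level = personas, .before = 1) |>
    mutate(
      delta_f1 = f1 - f1[1],
      delta_accuracy = accuracy - accuracy[1],
      delta_confidence = mean_confidence - mean_confidence[1]
    )
  new_ablation("persona", levels, baseline = personas[1])
}

#' Language sweep (multilingual conditions)
#'
#' Evaluates three conditions per language: `baseline`
#' (English description, English prompt), `cross` (translated description,
#' English prompt), and `same` (both translated). Deltas are taken against
#' the shared English baseline; dispersion is the per-entry-correctness
#' standard deviation.
#'
#' @param corpus A corpus tibble holding the English descriptions.
#' @param translations Tibble `id`, `language`, `text` with a translated
#'   description for every corpus entry and requested language; missing
#'   translations are an error listing the entries.
#' @param languages Language codes to evaluate (default fr, es, zh).
#' @inheritParams persona_sweep
#' @return A `soz_ablation` (axis `"language"`) with per-level `language`,
#'   `condition`, `f1`, `accuracy`, `sd_correct`, and `delta_f1`,
#'   `delta_accuracy` vs. baseline.
#' @export
language_sweep <- function(corpus, translations, languages = c("fr", "es", "zh"),
                           backend = mock_backend(),
                           lexicon = default_lexicon(), seed = 1L) {
  stopifnot(all(c("id", "language", "text") %in% names(translations)))
  base <- sweep_condition(corpus, prompt_spec("ZS"), backend, lexicon, seed) |>
    mutate(language = "en", condition = "baseline", .before = 1)
  rows <- list(base)
  for (lang in languages) {
    tr <- translations[translations$language == lang, ]
    missing <- setdiff(corpus$id, tr$id)
    if (length(missing)) {
      abort(sprintf(
        "Missing %s translation for %d entr%s (e.g. %s).",
        lang, length(missing), if (length(missing) == 1) "y" else "ies",
        paste(head(missing, 5), collapse = ", ")
      ))
    }
    translated <- corpus
    translated$text <- tr$text[match(corpus$id, tr$id)]
    translated$language <- lang
    for (cond in c("cross", "same")) {
      spec <- if (cond == "cross") {
        prompt_spec("ZS", language = "en", query_language = lang)
      } else {
        prompt_spec("ZS", language = lang)
      }
      rows <- c(rows, list(
        sweep_condition(translated, spec, backend, lexicon, seed) |>
          mutate(language = lang, condition = cond, .before = 1)
      ))
    }
  }
  levels <- bind_rows(rows) |>
    mutate(
      delta_f1 = f1 - f1[1],
      delta_accuracy = accuracy - accuracy[1]
    )
  new_ablation("language", levels, baseline = "en/baseline")
}
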