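#' Configuration for an evaluation grid
#'
#' One structured object holds every setting of a grid run so the manifest
#' can record it and cached responses can be matched to it. Defaults are
#' the harness's standard settings: all five strategies, temperature 0.2
#' (carried to live backends; the mock ignores it), 5 self-consistency
#' chains, 999 permutations and bootstrap resamples, 10 reliability bins.
#'
#' @param backend Backend name (resolved through [get_backend()]) or a
#'   `soz_backend` object.
#' @param strategies Prompt strategies to evaluate.
#' @param persona,language Prompt persona and language.
#' @param k Few-shot exemplar count.
#' @param n_perm Label permutations for the significance test.
#' @param n_boot Bootstrap resamples for the F1 interval.
#' @param bins Reliability bin count.
#' @param temperature Sampling temperature for live backends.
#' @param prob Calibration probability pairing (see [make_predictions()]).
#' @param seed Master seed; every stochastic component derives from it.
#' @return A `soz_run_config` list.
#' @export
run_config <- function(backend = "mock",
                       strategies = soz_strategies(),
                       persona = "AI assistant",
                       language = "en",
                       k = 5L,
                       n_perm = 999L,
                       n_boot = 999L,
                       bins = 10L,
                       temperature = 0.2,
                       prob = "predicted",
                       seed = 1L) {
  stopifnot(all(strategies %in% soz_strategies()), n_perm >= 1, n_boot >= 1, bins >= 2)
  structure(list(
    backend = if (inherits(backend, "soz_backend")) backend$name else backend,
    backend_object = if (inherits(backend, "soz_backend")) backend else NULL,
    strategies = strategies, persona = persona, language = language,
    k = as.integer(k), n_perm = as.integer(n_perm), n_boot = as.integer(n_boot),
    bins = as.integer(bins), temperature = temperature, prob = prob,
    seed = as.integer(seed)
  ), class = "soz_run_config")
}

config_hash <- function(config) {
  hashable <- config[setdiff(names(config), "backend_object")]
  rlang::hash(hashable)
}

#' Run the evaluation grid
#'
#' For each strategy: builds prompts, queries the backend (or replays a
#' response cache), parses responses, aggregates self-consistency chains,
#' and computes the full metric and significance set. When `outdir` is
#' given, all report files plus a manifest (config hash, seeds, package
#' version) are written; responses are appended to `responses.jsonl`
#' there. An existing manifest with a different config hash is refused
#' (mixed caches are not comparable — re-run into a clean directory).
#'
#' @param corpus A corpus tibble.
#' @param config A [run_config()].
#' @param outdir Optional output directory for reports and the response
#'   cache.
#' @param responses Optional responses tibble (e.g. from
#'   [read_response_cache()]) to replay instead of querying the backend.
#' @return A `soz_grid`: per-strategy `soz_eval` objects plus a summary
#'   table; see [glance.soz_grid()].
#' @export
run_grid <- function(corpus, config = run_config(), outdir = NULL, responses = NULL) {
  stopifnot(inherits(config, "soz_run_config"))
  backend <- config$backend_object %||% get_backend(config$backend)
  hash <- config_hash(config)
  cache <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    manifest_path <- file.path(outdir, "manifest.json")
    if (file.exists(manifest_path)) {
      old <- jsonlite::fromJSON(manifest_path)
      if (!identical(old$config_hash, hash)) {
        abort(paste(
          "Output directory holds results for a different configuration",
          sprintf("(hash %s vs %s).", old$config_hash, hash),
          "Refusing to mix caches; re-run into a clean directory."
        ))
      }
    }
    if (is.null(responses)) cache <- file.path(outdir, "responses.jsonl")
  }
  cells <- list()
  for (strategy in config$strategies) {
    spec <- prompt_spec(strategy,
      persona = config$persona, language = config$language, k = config$k
    )
    cell_responses <- NULL
    if (!is.null(responses)) {
      cell_responses <- responses[
        responses$strategy == strategy & responses$persona == config$persona, ]
      if (nrow(cell_responses) == 0) {
        abort(sprintf("Replay cache holds no responses for strategy %s.", strategy))
      }
    }
    ev <- evaluate_responses(corpus, spec, backend,
      responses = cell_responses, cache = cache,
      prob = config$prob, bins = config$bins,
      n_boot = config$n_boot, seed = config$seed,
      exemplar_seed = config$seed
    )
    sig <- significance_report(ev$predictions, n_perm = config$n_perm, seed = config$seed)
    cells[[strategy]] <- list(strategy = strategy, eval = ev, significance = sig)
  }
  grid <- structure(
    list(cells = cells, config = config, config_hash = hash, n = nrow(corpus)),
    class = "soz_grid"
  )
  if (!is.null(outdir)) write_reports(grid, outdir)
  grid
}

#' Summary table of a grid run
#' @param x A `soz_grid`.
#' @param ... Unused.
#' @return Tibble with one row per strategy (scores also as percent, the
#'   scale results tables are usually printed on).
#' @method glance soz_grid
#' @export
glance.soz_grid <- function(x, ...) {
  bind_rows(map(x$cells, function(cell) {
    g <- glance(cell$eval)
    s <- cell$significance
    tibble(
      backend = x$config$backend, strategy = cell$strategy,
      n = g$n, f1 = g$f1, f1_pct = 100 * g$f1,
      f1_lower = g$f1_lower, f1_upper = g$f1_upper,
      precision = g$precision, recall = g$recall, accuracy = g$accuracy,
      mean_confidence = g$mean_confidence, brier = g$brier,
      null_mu = s$mu, null_sigma = s$sigma, z = s$z, p = s$p,
      p_empirical = s$p_empirical
    )
  })) |>
    mutate(p_adj = bh_adjust(p))
}

#' @export
print.soz_grid <- function(x, ...) {
  cat(sprintf(
    "<soz_grid> backend: %s | n = %d | strategies: %s\n",
    x$config$backend, x$n, paste(names(x$cells), collapse = ", ")
  ))
  print(select(glance(x), strategy, f1_pct, mean_confidence, brier, z, p_adj))
  invisible(x)
}

#' Write the report files for a grid run
#'
#' Writes `metrics.csv` (one row per strategy), `significance.csv`
#' (mirroring the significance-table layout: score, null mean/sd, z, p,
#' adjusted p), `calibration.json` (reliability bins per strategy),
#' `summary.txt` (human-readable), and `manifest.json`. Regeneration from
#' the same grid object is byte-identical; no timestamps enter reports.
#'
#' @param grid A `soz_grid`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(grid, outdir) {
  if (!inherits(grid, "soz_grid") || length(grid$cells) == 0) {
    abort("Nothing to report: empty grid.")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- glance(grid)
  readr::write_csv(summary, file.path(outdir, "metrics.csv"), progress = FALSE)
  readr::write_csv(
    select(
      summary, backend, strategy, f1,
      mu = null_mu, sigma = null_sigma, z, p, p_adj, p_empirical
    ),
    file.path(outdir, "significance.csv"),
    progress = FALSE
  )
  calib <- map(grid$cells, function(cell) cell$eval$calibration)
  jsonlite::write_json(calib, file.path(outdir, "calibration.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(
    list(
      config_hash = grid$config_hash,
      config = grid$config[setdiff(names(grid$config), "backend_object")],
      n_entries = grid$n,
      package_version = as.character(utils::packageVersion("sozloc"))
    ),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  lines <- c(
    sprintf("Evaluation grid: backend %s, %d entries", grid$config$backend, grid$n),
    sprintf(
      "  %-7s F1 = %6.2f%% [%5.2f, %5.2f]  conf = %.3f  Brier = %.4f  z = %6.2f  p_adj = %.3g",
      summary$strategy, summary$f1_pct, 100 * summary$f1_lower, 100 * summary$f1_upper,
      summary$mean_confidence, summary$brier, summary$z, summary$p_adj
    )
  )
  writeLines(lines, file.path(outdir, "summary.txt"))
  invisible(outdir)
}

#' Write an ablation result to CSV
#' @param x A `soz_ablation`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ablation <- function(x, path) {
  stopifnot(inherits(x, "soz_ablation"))
  out <- x$levels
  for (nm in names(x$tests)) out[[nm]] <- x$tests[[nm]]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
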