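#' Responder backends
#'
#' A backend is the object the evaluation grid queries for raw response
#' text. The package ships a fully offline mock backend built on
#' [simulate_response()]; adapters for live language-model APIs can be
#' registered under a name and used interchangeably (they must raise a
#' transport error when unavailable, never fabricate a response).
#'
#' @param name Backend name used in caches and reports.
#' @param query Function `(entry, spec, chain_index) -> character(1)`.
#' @param config Optional list of backend settings (e.g. `temperature`,
#'   default 0.2, carried for live adapters; the mock ignores it).
#' @return A `soz_backend` object.
#' @export
backend <- function(name, query, config = list(temperature = 0.2)) {
  stopifnot(is.character(name), length(name) == 1, is.function(query))
  structure(list(name = name, query = query, config = config),
    class = "soz_backend"
  )
}

#' @rdname backend
#' @param params [responder_params()] for the simulated responder.
#' @export
mock_backend <- function(params = responder_params()) {
  backend(
    name = "mock",
    query = function(entry, spec, chain_index) {
      simulate_response(entry, spec, params, chain_index)
    },
    config = list(temperature = 0.2, responder = params)
  )
}

# package-level backend registry
the_backends <- new.env(parent = emptyenv())

#' Register / look up a backend by name
#' @param x A `soz_backend` (to register) or a backend name (to look up).
#' @return The backend, invisibly for `register_backend()`.
#' @export
register_backend <- function(x) {
  stopifnot(inherits(x, "soz_backend"))
  assign(x$name, x, envir = the_backends)
  invisible(x)
}

#' @rdname register_backend
#' @export
get_backend <- function(x) {
  if (inherits(x, "soz_backend")) return(x)
  if (!is.character(x) || !exists(x, envir = the_backends)) {
    abort(sprintf(
      "No backend registered under %s. Register one with register_backend().",
      sQuote(as.character(x)[1])
    ))
  }
  get(x, envir = the_backends)
}

#' Query a backend for one response chain
#'
#' Thin transport wrapper: dispatches the query and, when `cache` is given,
#' appends one JSON-lines record per query
#' (`entry_id, strategy, persona, language, chain_index, raw_text,
#' timestamp, backend`).
#'
#' @param backend A `soz_backend` or registered backend name.
#' @param entry One corpus row.
#' @param spec A [prompt_spec()].
#' @param chain_index Chain index (>= 1).
#' @param cache Optional path to a JSONL response cache.
#' @return Raw response text (character of length 1).
#' @export
backend_query <- function(backend, entry, spec, chain_index = 1L, cache = NULL) {
  backend <- get_backend(backend)
  raw <- backend$query(entry, spec, chain_index)
  if (!is.character(raw) || length(raw) != 1) {
    abort(sprintf("Backend %s returned a non-text response.", sQuote(backend$name)))
  }
  if (!is.null(cache)) {
    cache_append(cache, list(
      entry_id = as.character(entry$id)[1],
      strategy = spec$strategy,
      persona = spec$persona,
      language = spec$language,
      chain_index = as.integer(chain_index),
      raw_text = raw,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
      backend = backend$name
    ))
  }
  raw
}

cache_append <- function(path, record) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE)
  con <- file(path, open = "a", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(line, con, useBytes = TRUE)
  invisible(path)
}

#' Read a JSONL response cache
#' @param path Cache path.
#' @return Tibble with one row per cached query.
#' @export
read_response_cache <- function(path) {
  if (!file.exists(path)) abort(sprintf("Response cache not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("Response cache is empty: %s", path))
  recs <- map(lines, jsonlite::fromJSON)
  tibble(
    entry_id = map_chr(recs, "entry_id"),
    strategy = map_chr(recs, "strategy"),
    persona = map_chr(recs, "persona"),
    language = map_chr(recs, "language"),
    chain_index = map_int(recs, "chain_index"),
    raw_text = map_chr(recs, "raw_text"),
    timestamp = map_chr(recs, "timestamp"),
    backend = map_chr(recs, "backend")
  )
}
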