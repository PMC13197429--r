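# memoized default lexicon and per-language surface tables (the packaged
# TSV is read once per session, not once per response)
the_cache <- new.env(parent = emptyenv())

default_lexicon <- function() {
  if (is.null(the_cache$lexicon)) the_cache$lexicon <- region_lexicon()
  the_cache$lexicon
}

#' Multilingual region-name lexicon
#'
#' Maps surface region names in each supported language to the canonical
#' seven regions. Lookup is case- and diacritic-insensitive. The shipped
#' lexicon (a TSV resource: `language`, `surface`, `canonical`) covers
#' English, French, Spanish, and Chinese; supply your own file for other
#' languages.
#'
#' @param path Optional path to a lexicon TSV; defaults to the packaged one.
#' @return A `soz_lexicon` tibble with a normalized lookup key column.
#' @export
region_lexicon <- function(path = NULL) {
  path <- path %||% system.file("extdata", "region_lexicon.tsv", package = "sozloc")
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  stopifnot(all(c("language", "surface", "canonical") %in% names(df)))
  df$canonical <- match_regions(df$canonical)
  df$key <- normalize_surface(df$surface)
  structure(as_tibble(df), class = c("soz_lexicon", class(tibble())))
}

# lowercase + strip diacritics where transliteration is possible; non-Latin
# scripts (Chinese) fall through unchanged via the exact lowercase key
normalize_surface <- function(x) {
  x <- tolower(trimws(x))
  translit <- suppressWarnings(iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT"))
  ok <- !is.na(translit) & !grepl("?", translit, fixed = TRUE)
  # glibc transliterates accents to apostrophes ("lóbulo" -> "l'obulo"):
  # drop the residue so accented and plain spellings collide
  translit[ok] <- gsub("[^a-z0-9 ]", "", translit[ok])
  translit[!ok] <- x[!ok]
  stringr::str_squish(translit)
}

#' Map a surface region name to its canonical region
#'
#' @param name Surface name as produced by a responder.
#' @param language ISO language code; the lexicon must cover it. English is
#'   always tried as a fallback (responders often answer with English keys
#'   regardless of prompt language).
#' @param lexicon A [region_lexicon()]; defaults to the packaged one.
#' @return The canonical region name, or `NA_character_` when nothing
#'   matches (the caller records a defect).
#' @examples
#' canonicalize_region("lobe temporal", "fr")
#' canonicalize_region("TEMPORAL LOBE", "en")
#' @export
canonicalize_region <- function(name, language = "en", lexicon = default_lexicon()) {
  if (!language %in% lexicon$language) {
    abort(sprintf("Lexicon does not cover language %s.", sQuote(language)))
  }
  key <- normalize_surface(name)
  for (lang in unique(c(language, "en"))) {
    sub <- lexicon[lexicon$language == lang, ]
    hit <- match(key, sub$key)
    if (!is.na(hit)) return(sub$canonical[hit])
  }
  NA_character_
}

#' Preferred surface names for the seven regions in a language
#' @inheritParams canonicalize_region
#' @return Named character 7-vector (names = canonical regions).
#' @export
region_surface <- function(language = "en", lexicon = NULL) {
  if (is.null(lexicon)) {
    key <- paste0("surface_", language)
    if (is.null(the_cache[[key]])) {
      the_cache[[key]] <- region_surface(language, default_lexicon())
    }
    return(the_cache[[key]])
  }
  if (!language %in% lexicon$language) {
    abort(sprintf("Lexicon does not cover language %s.", sQuote(language)))
  }
  sub <- lexicon[lexicon$language == language, ]
  out <- map_chr(soz_regions(), function(r) sub$surface[match(r, sub$canonical)])
  setNames(out, soz_regions())
}

#' Serialize a likelihood vector to the standard JSON response format
#'
#' @param values Likelihoods over the 7 regions (named or in canonical
#'   order), in percent.
#' @param language Language for the region keys.
#' @param reasoning,sources Optional chain-of-thought fields.
#' @return A single JSON-formatted string.
#' @export
serialize_likelihoods <- function(values, language = "en", reasoning = NULL,
                                  sources = NULL) {
  values <- as_region_vector(values)
  surfaces <- region_surface(language)
  lines <- sprintf('  "%s": %s', surfaces, formatC(values, format = "f", digits = 2))
  if (!is.null(reasoning)) {
    lines <- c(lines, sprintf('  "Reasoning": %s', jsonlite::toJSON(unname(reasoning), auto_unbox = TRUE)))
  }
  if (!is.null(sources)) {
    lines <- c(lines, sprintf('  "Sources": %s', jsonlite::toJSON(as.character(sources))))
  }
  paste0("{\n", paste(lines, collapse = ",\n"), "\n}")
}

#' Parse a raw responder output into structured likelihoods
#'
#' Extracts the first balanced `{...}` block (chain-of-thought responses
#' may embed prose around the dictionary), validates it, and canonicalizes
#' region keys through the lexicon. Numeric values are accepted with or
#' without a `%` suffix. Missing, non-numeric, or ambiguous values (such as
#' `"None"`) are assigned a likelihood of 0 with a defect record. Values
#' above 100 are kept but flagged. Nothing throws: every failure mode is
#' encoded in `status`/`defects`, and a response from which no region value
#' can be recovered comes back as `status = "failed"` with an all-zero
#' vector (scored downstream as an incorrect prediction with confidence 0).
#'
#' @param raw Raw response text (any text accepted).
#' @param language Response language (for region-name lookup).
#' @param lexicon A [region_lexicon()].
#' @return A `soz_parsed` list: `likelihoods` (named numeric 7-vector, in
#'   percent), `reasoning`, `sources`, `status` (`"ok"`, `"partial"`,
#'   `"failed"`), `defects` (character vector).
#' @examples
#' raw <- serialize_likelihoods(c(60, 10, 5, 10, 5, 5, 5))
#' parse_response(raw)$status
#' @export
parse_response <- function(raw, language = "en", lexicon = default_lexicon()) {
  defects <- character()
  likelihoods <- setNames(numeric(7), soz_regions())
  recovered <- setNames(logical(7), soz_regions())
  reasoning <- NA_character_
  sources <- character()

  raw <- paste(as.character(raw), collapse = "\n")
  trimmed <- trimws(raw)
  parsed <- NULL
  # fast path: the response is the bare dictionary (no surrounding prose)
  if (startsWith(trimmed, "{") && endsWith(trimmed, "}")) {
    parsed <- tryCatch(jsonlite::fromJSON(trimmed, simplifyVector = TRUE),
      error = function(e) NULL
    )
  }
  pairs <- NULL
  if (is.null(parsed) || is.null(names(parsed))) {
    block <- first_balanced_block(raw)
    if (is.null(block)) {
      defects <- c(defects, "no JSON dictionary found")
      pairs <- regex_pairs(raw)
      if (nrow(pairs) == 0) {
        return(new_parsed(likelihoods, reasoning, sources, "failed", defects))
      }
    } else {
      parsed <- tryCatch(jsonlite::fromJSON(block, simplifyVector = TRUE),
        error = function(e) NULL
      )
      if (is.null(parsed) || is.null(names(parsed))) {
        defects <- c(defects, "malformed JSON; fell back to key-value extraction")
        pairs <- regex_pairs(raw)
        parsed <- NULL
      }
    }
  }
  if (!is.null(parsed) && !is.null(names(parsed))) {
    pairs <- tibble(
      key = names(parsed),
      value = map_chr(parsed, function(v) paste(format(v, scientific = FALSE), collapse = " | "))
    )
  }

  for (i in seq_len(nrow(pairs))) {
    key <- pairs$key[i]
    val <- pairs$value[i]
    if (tolower(key) == "reasoning") {
      reasoning <- val
      next
    }
    if (tolower(key) == "sources") {
      sources <- strsplit(val, " | ", fixed = TRUE)[[1]]
      next
    }
    canon <- canonicalize_region(key, language, lexicon)
    if (is.na(canon)) {
      defects <- c(defects, sprintf("unrecognized key %s", sQuote(key)))
      next
    }
    num <- parse_likelihood_value(val)
    if (is.na(num)) {
      defects <- c(defects, sprintf(
        "non-numeric value %s for %s; 0%% assigned", sQuote(val), canon
      ))
      likelihoods[canon] <- 0
      recovered[canon] <- TRUE
      next
    }
    if (num < 0) {
      defects <- c(defects, sprintf("negative likelihood for %s; 0%% assigned", canon))
      num <- 0
    }
    if (num > 100) {
      defects <- c(defects, sprintf("likelihood above 100%% for %s kept as-is", canon))
    }
    likelihoods[canon] <- num
    recovered[canon] <- TRUE
  }

  missing <- soz_regions()[!recovered]
  if (length(missing) && length(missing) < 7) {
    defects <- c(defects, sprintf("missing region %s; 0%% assigned", missing))
  }
  status <- if (!any(recovered)) {
    if (!length(defects)) defects <- "no region value recovered"
    "failed"
  } else if (length(defects) == 0 && all(recovered)) {
    "ok"
  } else {
    "partial"
  }
  new_parsed(likelihoods, reasoning, sources, status, defects)
}

new_parsed <- function(likelihoods, reasoning, sources, status, defects) {
  structure(
    list(
      likelihoods = likelihoods, reasoning = reasoning, sources = sources,
      status = status, defects = defects
    ),
    class = "soz_parsed"
  )
}

#' @export
print.soz_parsed <- function(x, ...) {
  cat(sprintf("<soz_parsed> status: %s\n", x$status))
  print(round(x$likelihoods, 2))
  if (length(x$defects)) cat("defects:", paste(x$defects, collapse = "; "), "\n")
  invisible(x)
}

# first balanced {...} block, brace-counting outside JSON strings;
# returns NULL when no block opens or the block never closes
first_balanced_block <- function(raw) {
  chars <- strsplit(raw, "", fixed = TRUE)[[1]]
  depth <- 0L
  start <- NA_integer_
  in_string <- FALSE
  escaped <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_string) {
      if (escaped) {
        escaped <- FALSE
      } else if (ch == "\\") {
        escaped <- TRUE
      } else if (ch == '"') {
        in_string <- FALSE
      }
      next
    }
    if (ch == '"') {
      in_string <- TRUE
    } else if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}") {
      if (depth > 0L) {
        depth <- depth - 1L
        if (depth == 0L) return(substr(raw, start, i))
      }
    }
  }
  NULL
}

# lenient key-value extraction for malformed responses:  "key": value
regex_pairs <- function(raw) {
  m <- stringr::str_match_all(
    raw, '"([^"\n]+)"\\s*:\\s*("[^"\n]*"?|\\[[^\\]]*\\]?|[^,\n{}]*)'
  )[[1]]
  if (nrow(m) == 0) return(tibble(key = character(), value = character()))
  value <- trimws(m[, 3])
  value <- gsub('^\\[|\\]$', "", value)
  value <- gsub('^"|"$', "", value)
  tibble(key = m[, 2], value = value)
}

# numeric likelihood, tolerating a % suffix; NA when not numeric
parse_likelihood_value <- function(x) {
  x <- trimws(gsub("%\\s*$", "", trimws(x)))
  if (!grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", x)) {
    return(NA_real_)
  }
  suppressWarnings(as.numeric(x))
}

#' Parse a table of cached responses
#'
#' Vectorized wrapper around [parse_response()] for a response-cache tibble
#' (see [read_response_cache()]).
#'
#' @param responses Tibble with at least `entry_id`, `chain_index`,
#'   `raw_text`, `language`.
#' @param lexicon A [region_lexicon()].
#' @return Tibble: `entry_id`, `chain_index`, `likelihoods` (list-column of
#'   named 7-vectors), `status`, `defects` (list-column), `reasoning`.
#' @export
parse_responses <- function(responses, lexicon = default_lexicon()) {
  parsed <- map2(responses$raw_text, responses$language, function(raw, lang) {
    parse_response(raw, language = lang, lexicon = lexicon)
  })
  tibble(
    entry_id = responses$entry_id,
    chain_index = responses$chain_index,
    likelihoods = map(parsed, "likelihoods"),
    status = map_chr(parsed, "status"),
    defects = map(parsed, "defects"),
    reasoning = map_chr(parsed, "reasoning")
  )
}
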