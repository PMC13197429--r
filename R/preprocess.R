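#' Text preprocessing rules for semiology descriptions
#'
#' Free-text seizure descriptions are normalized before evaluation:
#' clinical abbreviations are expanded, common misspellings corrected, and
#' uninformative boilerplate words removed. The rule sets shipped with the
#' package are a minimal, editable starter list (plain-text resources under
#' `inst/extdata/preprocess/`); corpora with their own conventions should
#' supply their own maps.
#'
#' Abbreviation expansion is case-sensitive (abbreviations are conventionally
#' upper-case); spelling correction and stop-term removal are
#' case-insensitive. All substitutions are whole-word. The resulting
#' transformation is idempotent provided no rule output reintroduces a rule
#' key, which holds for the shipped defaults and is checked by the test
#' suite.
#'
#' @param abbreviations Named character vector (`c(LOC = "loss of
#'   consciousness")`) or a two-column data frame (`from`, `to`).
#' @param spellings Same shape as `abbreviations`.
#' @param stop_terms Character vector of words to drop.
#' @return An object of class `soz_rules`.
#' @examples
#' r <- preprocess_rules(abbreviations = c(LOC = "loss of consciousness"))
#' preprocess_text("LOC with automatisms", r)
#' @export
preprocess_rules <- function(abbreviations = default_rule("abbreviations"),
                             spellings = default_rule("spellings"),
                             stop_terms = default_rule("stop_terms")) {
  rules <- list(
    abbreviations = as_rule_map(abbreviations),
    spellings = as_rule_map(spellings),
    stop_terms = as.character(stop_terms)
  )
  structure(rules, class = "soz_rules")
}

#' @export
print.soz_rules <- function(x, ...) {
  cat(sprintf(
    "<soz_rules> %d abbreviation(s), %d spelling(s), %d stop term(s)\n",
    length(x$abbreviations), length(x$spellings), length(x$stop_terms)
  ))
  invisible(x)
}

as_rule_map <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("from", "to") %in% names(x)))
    return(setNames(as.character(x$to), as.character(x$from)))
  }
  if (is.null(x)) return(setNames(character(), character()))
  if (is.null(names(x))) abort("Rule maps must be named (from = to).")
  setNames(as.character(x), names(x))
}

default_rule <- function(which) {
  dir <- system.file("extdata", "preprocess", package = "sozloc")
  if (which == "stop_terms") {
    lines <- readLines(file.path(dir, "stop_terms.txt"), encoding = "UTF-8")
    lines <- trimws(lines)
    return(lines[nzchar(lines) & !startsWith(lines, "#")])
  }
  readr::read_tsv(file.path(dir, paste0(which, ".tsv")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
}

#' Normalize a semiology description
#'
#' Applies, in order: abbreviation expansion, spelling correction, stop-term
#' removal, whitespace collapsing. Deterministic and idempotent for
#' non-self-referential rule sets (see [preprocess_rules()]).
#'
#' @param text Character vector of raw descriptions (empty strings allowed).
#' @param rules A [preprocess_rules()] object.
#' @return Character vector of normalized descriptions.
#' @export
preprocess_text <- function(text, rules = preprocess_rules()) {
  stopifnot(inherits(rules, "soz_rules"))
  out <- as.character(text)
  out[is.na(out)] <- ""
  for (i in seq_along(rules$abbreviations)) {
    out <- gsub(
      word_pattern(names(rules$abbreviations)[i]),
      rules$abbreviations[[i]], out, perl = TRUE
    )
  }
  for (i in seq_along(rules$spellings)) {
    out <- gsub(
      word_pattern(names(rules$spellings)[i]),
      rules$spellings[[i]], out, perl = TRUE, ignore.case = TRUE
    )
  }
  if (length(rules$stop_terms)) {
    pat <- word_pattern(rules$stop_terms)
    out <- gsub(pat, "", out, perl = TRUE, ignore.case = TRUE)
  }
  stringr::str_squish(out)
}

# whole-word regex for one or more literal terms; \b fails for terms ending
# in punctuation (e.g. "w/"), so use lookarounds on non-word characters
word_pattern <- function(terms) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", terms)
  sprintf("(?<![\\w])(%s)(?![\\w])", paste(esc, collapse = "|"))
}

#' Count whitespace-delimited words
#'
#' Word counts drive the description-length analysis. The rule is the
#' simplest reproducible one: the number of whitespace-separated tokens in
#' the preprocessed text (0 for empty text).
#'
#' @param text Character vector (assumed already preprocessed).
#' @return Integer vector.
#' @export
count_words <- function(text) {
  ifelse(nzchar(trimws(text)), stringr::str_count(stringr::str_squish(text), "\\S+"), 0L)
}
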