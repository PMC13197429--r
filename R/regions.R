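#' The seven canonical seizure-onset-zone regions
#'
#' Localization targets are restricted to seven major brain regions. Their
#' order is fixed package-wide: likelihood vectors are laid out in this order
#' and argmax / voting ties are broken by it.
#'
#' @return A character vector of length 7.
#' @examples
#' soz_regions()
#' @export
soz_regions <- function() {
  c(
    "Temporal Lobe", "Frontal Lobe", "Cingulate Gyrus", "Parietal Lobe",
    "Occipital Lobe", "Insula", "Hypothalamus"
  )
}

#' Number of canonical regions
#' @return Integer, 7.
#' @keywords internal
n_regions <- function() 7L

# validate a character vector of region names; returns canonical-cased names
# or aborts naming the offending values (and optionally the row)
match_regions <- function(x, row = NULL) {
  regions <- soz_regions()
  idx <- match(tolower(trimws(x)), tolower(regions))
  if (anyNA(idx)) {
    bad <- x[is.na(idx)]
    where <- if (is.null(row)) "" else sprintf(" (row %s)", row)
    abort(sprintf(
      "Unknown region name%s: %s. Regions must be one of: %s.",
      where, paste(sQuote(bad), collapse = ", "),
      paste(regions, collapse = ", ")
    ))
  }
  regions[idx]
}

# coerce a named numeric vector into canonical 7-region order; missing names
# are an error. Used at module boundaries that accept user-supplied vectors.
as_region_vector <- function(x) {
  regions <- soz_regions()
  if (is.null(names(x))) {
    if (length(x) != n_regions()) {
      abort("An unnamed likelihood vector must have exactly 7 values.")
    }
    return(setNames(as.numeric(x), regions))
  }
  nm <- match_regions(names(x))
  if (anyDuplicated(nm)) abort("Duplicate region names in likelihood vector.")
  if (length(x) != n_regions()) {
    abort("A likelihood vector must cover all 7 regions.")
  }
  setNames(as.numeric(x)[match(regions, nm)], regions)
}
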