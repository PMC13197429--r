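#' Median-based majority voting over self-consistency chains
#'
#' Self-consistency elicits five independent likelihood vectors for the
#' same query and selects the single most consistent one. For each region
#' `i` the median of its five likelihoods is computed, the adjusted
#' likelihood is the absolute deviation from that median,
#' `A[i, j] = |L[i, j] - median_i(L[i, ])|`, and the winning chain `W`
#' minimizes the column sum `sum_i A[i, j]`. The winner's vector is
#' returned unchanged — voting selects a chain, it never averages. Ties on
#' the minimal adjusted sum go to the smallest chain index, so the result
#' is deterministic and order-stable. Chains that failed to parse must be
#' entered as all-zero vectors (the 5-chain contract is kept, not pruned).
#'
#' @param chains A 7 x 5 numeric matrix (regions in canonical order x
#'   chains), or a list of exactly 5 likelihood vectors as accepted by
#'   `parse_response()` outputs.
#' @return A list of class `soz_vote`: `winner` (chain index in 1..5),
#'   `likelihoods` (the winning 7-vector), `medians`, `adjusted` (the 7 x 5
#'   deviation matrix), `adjusted_sums`.
#' @examples
#' chains <- replicate(5, c(60, 10, 5, 10, 5, 5, 5)) + matrix(rnorm(35), 7)
#' median_vote(abs(chains))$winner
#' @export
median_vote <- function(chains) {
  if (is.list(chains)) {
    if (length(chains) != 5) abort("Self-consistency requires exactly 5 chains.")
    chains <- vapply(chains, as_region_vector, numeric(7))
  }
  chains <- as.matrix(chains)
  if (nrow(chains) != 7 || ncol(chains) != 5) {
    abort("Self-consistency requires a 7 x 5 likelihood matrix (got a different shape).")
  }
  if (any(chains < 0)) abort("Likelihoods must be nonnegative.")
  medians <- apply(chains, 1, median)
  adjusted <- abs(chains - medians)
  sums <- colSums(adjusted)
  winner <- which.min(sums) # which.min takes the first minimum: lowest index
  likelihoods <- setNames(chains[, winner], soz_regions())
  structure(list(
    winner = as.integer(winner), likelihoods = likelihoods,
    medians = setNames(medians, soz_regions()),
    adjusted = adjusted, adjusted_sums = sums
  ), class = "soz_vote")
}

#' @export
print.soz_vote <- function(x, ...) {
  cat(sprintf(
    "<soz_vote> winner: chain %d (adjusted sums: %s)\n",
    x$winner, paste(signif(x$adjusted_sums, 4), collapse = ", ")
  ))
  invisible(x)
}
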