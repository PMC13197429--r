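#' Parameters for the simulated likelihood responder
#'
#' The mock backend emits the structured JSON dictionary the harness
#' expects from a language model, with controllable accuracy, confidence
#' concentration, calibration, and output malformation. It makes every
#' downstream stage testable fully offline; it does not imitate any
#' specific model's behavior.
#'
#' Two accuracy-control modes are supported:
#' * `"calibrated"`: per response a confidence `c` is drawn uniformly on
#'   `conf_range`; with probability `c` the top region is sampled from the
#'   entry's truth set, otherwise uniformly from its complement, and the top
#'   region receives `100 * c` percent. Stated likelihood then equals the
#'   probability of being correct, so reliability is diagonal by
#'   construction and the expected Brier score is `E[c(1 - c)]`.
#' * `"fixed"`: the hit probability and the top likelihood are both the
#'   constant `accuracy`.
#'
#' @param mode `"calibrated"` or `"fixed"`.
#' @param accuracy Hit probability for `"fixed"` mode.
#' @param conf_range Confidence bounds `(c_lo, c_hi)` for `"calibrated"`
#'   mode; `c_lo` must exceed 1/7 so the stated top region stays the argmax.
#' @param concentration Nonnegative spread parameter for the non-winning
#'   mass: 0 (default) spreads it evenly; positive values draw
#'   Dirichlet(`concentration`) shares, adding likelihood noise.
#' @param malform_rate Probability of injecting a structural defect into the
#'   serialized response.
#' @param defect_mix Named weights over defect kinds `missing_key`,
#'   `none_value`, `non_numeric`, `broken_json`; normalized to sum to 1.
#' @param effect Optional function `(entry, spec) -> delta` added to the hit
#'   probability (clamped to \[0, 1\]); used to plant persona, language, or
#'   length effects for the ablation drivers.
#' @param seed Integer seed. Responses are deterministic given
#'   `(seed, entry id, chain index)`.
#' @return A `soz_responder_params` list.
#' @export
responder_params <- function(mode = c("calibrated", "fixed"),
                             accuracy = 0.6,
                             conf_range = c(0.2, 1),
                             concentration = 0,
                             malform_rate = 0,
                             defect_mix = c(
                               missing_key = 0.25, none_value = 0.25,
                               non_numeric = 0.25, broken_json = 0.25
                             ),
                             effect = NULL,
                             seed = 1) {
  mode <- match.arg(mode)
  stopifnot(
    accuracy >= 0, accuracy <= 1,
    length(conf_range) == 2, conf_range[1] >= 0, conf_range[2] <= 1,
    conf_range[1] < conf_range[2],
    concentration >= 0, malform_rate >= 0, malform_rate <= 1
  )
  kinds <- c("missing_key", "none_value", "non_numeric", "broken_json")
  if (is.null(names(defect_mix)) || !all(names(defect_mix) %in% kinds)) {
    abort("defect_mix must be named with kinds: missing_key, none_value, non_numeric, broken_json.")
  }
  mix <- setNames(numeric(length(kinds)), kinds)
  mix[names(defect_mix)] <- defect_mix
  if (sum(mix) <= 0) abort("defect_mix must have positive total weight.")
  mix <- mix / sum(mix)
  if (mode == "calibrated" && conf_range[1] <= 1 / 7) {
    warn("conf_range[1] <= 1/7: the stated top region may not be the argmax.")
  }
  structure(list(
    mode = mode, accuracy = accuracy, conf_range = conf_range,
    concentration = concentration, malform_rate = malform_rate,
    defect_mix = mix, effect = effect, seed = as.integer(seed)
  ), class = "soz_responder_params")
}

# deterministic 31-bit hash of a string (polynomial rolling hash); used to
# derive per-(seed, entry, chain) RNG streams without external dependencies
string_hash <- function(x) {
  p <- 2147483629 # prime < 2^31
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% p
  as.integer(h)
}

entry_seed <- function(seed, id, chain_index) {
  p <- 2147483629
  as.integer((string_hash(id) + (seed %% p) * 92821 + chain_index * 613) %% p)
}

# minimal seed scope for the per-response hot path: save/seed/restore the
# global RNG state without the generality (and overhead) of withr
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate one raw responder output
#'
#' Draws a response for one corpus entry under the model described in
#' [responder_params()] and serializes it as the standard JSON likelihood
#' dictionary (with `Reasoning` and `Sources` fields for chain-of-thought
#' strategies). Region keys use the surface names of the prompt language.
#' With probability `malform_rate` a structural defect is injected into the
#' serialized text, after serialization, so defects exercise the real
#' parser paths.
#'
#' @param entry One corpus row (a list or one-row tibble with `id` and
#'   `truth`).
#' @param spec A [prompt_spec()]; controls language and whether
#'   reasoning/source fields are emitted.
#' @param params A [responder_params()] object.
#' @param chain_index Positive chain index (self-consistency uses 1..5).
#' @return A single raw response string.
#' @export
simulate_response <- function(entry, spec = prompt_spec("ZS"), params = responder_params(),
                              chain_index = 1L) {
  stopifnot(inherits(params, "soz_responder_params"), chain_index >= 1)
  id <- as.character(entry$id)[1]
  truth <- if (is.list(entry$truth)) entry$truth[[1]] else entry$truth
  if (length(truth) == 0) abort("Entry has an empty truth set.")
  regions <- soz_regions()
  with_local_seed(entry_seed(params$seed, id, chain_index), {
    conf <- if (params$mode == "calibrated") {
      runif(1, params$conf_range[1], params$conf_range[2])
    } else {
      params$accuracy
    }
    hit_prob <- conf
    if (!is.null(params$effect)) {
      hit_prob <- min(1, max(0, hit_prob + params$effect(entry, spec)))
    }
    hit <- runif(1) < hit_prob
    top <- if (hit) {
      truth[sample.int(length(truth), 1)]
    } else {
      complement <- setdiff(regions, truth)
      complement[sample.int(length(complement), 1)]
    }
    values <- setNames(numeric(7), regions)
    values[top] <- 100 * conf
    rest <- setdiff(regions, top)
    shares <- if (params$concentration > 0) {
      g <- rgamma(6, shape = params$concentration)
      if (sum(g) == 0) rep(1 / 6, 6) else g / sum(g)
    } else {
      rep(1 / 6, 6)
    }
    values[rest] <- 100 * (1 - conf) * shares
    raw <- serialize_likelihoods(values,
      language = spec$language,
      reasoning = if (is_cot(spec$strategy)) {
        sprintf("Synthetic reasoning chain %d for entry %s.", chain_index, id)
      },
      sources = if (is_cot(spec$strategy)) {
        "Synthetic Reference et al. (2024), synthetic source."
      }
    )
    if (runif(1) < params$malform_rate) {
      kind <- sample(names(params$defect_mix), 1, prob = params$defect_mix)
      raw <- inject_defect(raw, kind, language = spec$language)
    }
    raw
  })
}

# structural defect injection by string surgery on the serialized response
inject_defect <- function(raw, kind, language = "en") {
  surfaces <- region_surface(language)
  victim <- surfaces[sample.int(length(surfaces), 1)]
  line_pat <- sprintf('[ \t]*"%s": [0-9.]+,?', victim)
  switch(kind,
    missing_key = {
      out <- sub(paste0(line_pat, "\n"), "", raw)
      fix_trailing_comma(out)
    },
    none_value = sub(
      sprintf('("%s": )[0-9.]+', victim), '\\1"None"', raw
    ),
    non_numeric = sub(
      sprintf('("%s": )[0-9.]+', victim), '\\1"high"', raw
    ),
    broken_json = substr(raw, 1, max(2, floor(nchar(raw) * 0.6))),
    abort(sprintf("Unknown defect kind: %s", kind))
  )
}

# removing the last likelihood line can leave a dangling comma before "}"
fix_trailing_comma <- function(x) gsub(",(\\s*)\\}", "\\1}", x)
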