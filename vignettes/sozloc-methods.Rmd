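---
title: "Evaluating likelihood-eliciting responders for seizure onset zone localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating likelihood-eliciting responders for seizure onset zone localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sozloc)
```

## The task

A seizure semiology is a free-text description of what happens during an
epileptic seizure. Experienced epileptologists use such descriptions to
hypothesize where in the brain a seizure originates — the seizure onset
zone (SOZ). `sozloc` evaluates systems that attempt the same mapping
probabilistically: given a semiology `S` embedded in a prompt with a
persona `P`, a query `Q`, and an instruction `I`, a responder must return
a JSON dictionary assigning a likelihood (in percent) to each of seven
canonical regions — temporal lobe, frontal lobe, cingulate gyrus,
parietal lobe, occipital lobe, insula, and hypothalamus. The region order
is fixed package-wide; it defines the layout of every likelihood vector
and breaks all ties (argmax, voting) deterministically.

Ground truth is multi-label: an entry may be linked to more than one
region (clinically, several resections can abolish the same semiology).
A single-region prediction is counted correct when it lies anywhere in
the truth set; this is also the reading under which a constant
majority-class predictor defines the chance-level baseline
(`naive_baseline()` reports both the inclusion accuracy and the weighted
F1 of that constant predictor, with accuracy as the headline number).

## Prompt strategies

Five strategies are built by `prompt_spec()` / `build_prompt()`:

* **ZS** — persona prefix (`"you are a {persona}"`, template preserved
  verbatim), the JSON-format instruction over the seven region names, and
  the query.
* **FS** — adds `K = 5` worked exemplars. The selection rule is not part
  of the published design, so the package samples uniformly without
  replacement, stratified across primary truth regions when feasible,
  always excluding the query entry (a hard leakage guard).
* **CoT** — adds the literal sentence *"Solve the problem in step by step
  manner"* and requires `Reasoning` and `Sources` keys in the dictionary.
* **FS-CoT** — few-shot exemplars whose outputs carry expert reasoning
  text. The shipped reasoning lines are clearly marked placeholders
  (`inst/extdata/prompts/fscot_reasoning_en.txt`): substitute text
  written by a clinician for real use.
* **SC** — a chain-of-thought prompt answered by five independent chains,
  aggregated by median voting (below).

Prompt resources (instruction, chain-of-thought sentence, region surface
names) ship per language for English, French, Spanish, and Chinese. The
cross-language condition swaps only the semiology text
(`query_language`), leaving the surrounding prompt in English.

## Self-consistency voting

With five chains, each region `i` contributes likelihoods
`L[i, 1..5]`. The adjusted likelihood is the absolute deviation from the
per-region median, `A[i, j] = |L[i, j] − median_i|`, and the winning
chain minimizes `sum_i A[i, j]`. The winner's vector is returned
unchanged — the vote selects a chain rather than averaging, so the output
is always one of the actual responses. The median of five values is the
middle order statistic (no interpolation), ties go to the lowest chain
index, and chains that failed to parse stay in the pool as all-zero
vectors so the five-chain contract is never silently violated.

## Scoring

**Correctness.** The prediction is the argmax region. Per-class one-vs-rest
precision, recall, and F1 are averaged with weights proportional to class
support. For multi-label entries one consistent reading is adopted: a
correct prediction credits the matched truth region; an incorrect one
charges the false negative to the first-listed truth region and the false
positive to the predicted region. An all-zero vector (failed parse) is a
designated no-prediction: always incorrect, probability 0, confidence 0 —
a parse failure can never inflate accuracy or confidence.

**Confidence.** The elicited vector is renormalized (responders are not
forced to emit values summing to 100) and scored with Shannon entropy in
bits, `H = −Σ p log2 p` with `0·log 0 = 0`. `H` ranges from 0 (one-hot)
to `log2 7 = 2.807` (uniform); confidence is `C = 1 − H / log2 7`. A
zero-mass vector takes `C = 0` by convention.

**Calibration.** Predictions are binned into `M` equal-width probability
bins `((m−1)/M, m/M]`; `M = 10` by default (a conventional choice — the
bin count is configurable). Per bin, the fraction of correct predictions
is compared with the mean stated probability; the Brier score
`mean((p − y)^2)` summarizes the same alignment. Two pairings of `p` are
supported: the default uses the likelihood of the *predicted* (argmax)
region against the right/wrong outcome, which is the pairing under which
"fraction of positives per confidence bin" is well defined; a switch
(`prob = "true"`) instead uses the likelihood assigned to the truth
region. Probability 0 is kept in the bottom bin rather than discarded so
failed parses remain visible in the reliability diagram.

**Uncertainty and significance.** Bootstrap intervals (999 resamples of
entries by default) are percentile intervals. The chance baseline for a
fixed prediction set is built by permuting the truth labels as intact
sets 999 times and recomputing the weighted F1; the observed score is
standardized as `z = (x − μ)/σ` with a two-sided normal p-value, and the
empirical exceedance rank `(1 + #{null ≥ x})/(n_perm + 1)` is reported
alongside. Degenerate nulls (`σ = 0`) are flagged rather than divided by.
Families of p-values are adjusted with the Benjamini–Hochberg step-up
(`stats::p.adjust`); note the step-up is not idempotent, so adjusted
values are never re-adjusted. Proportions (e.g. reasoning-evaluation
correctness rates) are compared with a pooled two-proportion z-test.

## The synthetic corpus and mock responder

Everything downstream of a backend is testable offline because the
package ships both a corpus generator and a simulated responder. These
emulate the *structure* of the study conditions, not clinical content:

* **Corpus** (`corpus_params()`): 1,269 entries by default with the
  temporal lobe as majority class at a 0.3821 primary-label share. The
  published corpus states only the majority share; the remaining profile
  (frontal 0.26, parietal 0.11, occipital 0.08, insula 0.07, cingulate
  0.06, hypothalamus 0.0379) was fixed once as a clinically plausible
  imbalance ordering. Entries gain a second truth region with probability
  0.1 (multi-label fractions are not published; a modest minority is
  realistic). Word counts follow `1 + NB(size 2, mean 11)`, giving the
  short, right-skewed lengths typical of symptom phrases (range ~1–60).
  Texts are random draws from a small semiology-flavored vocabulary —
  they exercise tokenization and length handling, not language
  understanding, which is exactly what a language-blind mock consumes.
* **Responder** (`responder_params()`): in calibrated mode a confidence
  `c ~ Uniform(c_lo, c_hi)` is drawn per response; the top region is
  sampled from the truth set with probability `c` and receives `100·c`
  percent, the remaining mass spread evenly (a Dirichlet jitter is
  available via `concentration`, off by default so the analytic oracles
  stay exact). Stated probability then equals the probability of being
  correct, so reliability is diagonal by construction, accuracy converges
  to `E[c]`, and the Brier score to `E[c(1−c)]` — closed forms the test
  suite checks (0.60 and 0.18667 for `Uniform(0.2, 1)`). The lower bound
  must exceed 1/7 or the stated top region would not be the argmax.
  Defects (missing key, `"None"`, non-numeric token, truncated JSON) are
  injected *after* serialization at rate `malform_rate`, so they exercise
  the real parser paths; a truncated dictionary is often partially
  recoverable, hence the malformation rate is recovered as the fraction
  of non-clean (`status != "ok"`) parses. An optional `effect` hook adds
  a per-(entry, spec) shift to the hit probability, which is how the test
  suite plants persona, language, and length effects to verify the
  ablation drivers recover them.

Passing tests on this mock demonstrate that the *measurement machinery* —
parsing, voting, scoring, calibration, significance, ablation drivers —
is correct and unbiased at the study's scale. They say nothing about how
any real language model performs; live backends plug in behind
`backend()`/`register_backend()` and are deliberately outside the test
surface.

## Ablation drivers

All three drivers reuse the single scoring path (`evaluate_responses()`),
so a sweep is never scored differently from the main grid.

* **Length** (`length_analysis()`): per-entry scores are grouped into six
  half-open word-count bins `[x, y)`; defaults are corpus sextile edges
  (the published edges live in supplementary material; pass `edges` to
  override). Differences across bins are tested with Kruskal–Wallis. To
  rule out sampling artifacts, entries are reassigned to bins at random
  (bin sizes preserved exactly) `n_shuffle` times and the observed bin
  means are compared against the pooled surrogate bin means with a
  two-sample Kolmogorov–Smirnov test. Simulation at n = 1269 shows this
  detects a planted 0.8/0.4/0.8 U-profile essentially always while
  staying conservative under a length-blind responder.
* **Persona** (`persona_sweep()`): zero-shot only (so few-shot exemplars
  cannot confound the comparison), deltas against the first persona
  ("AI assistant" in the default sweep of increasing specialization).
* **Language** (`language_sweep()`): English baseline, cross-language
  (translated description, English prompt), and same-language (both
  translated) per language, with translations supplied as data — the
  package does not machine-translate.

## Numerical conventions and edge cases

* Argmax and voting ties: canonical region order / lowest chain index.
* Length bins are half-open `[x, y)`; a word count outside the covered
  range is an explicit error, and empty bins are flagged and excluded
  from tests.
* Likelihoods above 100 are kept (argmax still defined) but flagged as
  defects; negative values are floored to 0 with a defect.
* Preprocessing (abbreviation expansion, spelling correction, stop-term
  removal) is idempotent provided no rule output reintroduces a rule key;
  the shipped starter rules satisfy this and the suite checks it. Word
  count is the whitespace-token count of the preprocessed text — the
  simplest reproducible rule.
* Every stochastic component takes an explicit seed; mock responses are
  deterministic per `(seed, entry id, chain index)`, so two grid runs
  with the same configuration are byte-identical, and re-scoring from the
  JSON-lines response cache reproduces a live run exactly.

## Problem sizes used by the checks

The test suite validates parameter recovery with 10,000 calibrated
responses; type-I error with 200 null simulations of 300 entries at 200
permutations each; voting against brute force on 200 random 7×5
matrices; the weighted-F1 path against an independent confusion-count
oracle on 500-entry corpora (to 1e−12); and ablation error rates over 30
simulations per condition at n = 1269. These sizes were chosen to give
3-standard-error margins on every recovered parameter while keeping the
default check run comfortably short.

## Limitations

* The synthetic corpus contains no clinical language; nothing here
  validates medical plausibility of any responder.
* The real curated corpus (Zenodo accession 10.5281/zenodo.4606589) is
  not redistributable with the package. `read_corpus()` ingests it once
  exported to the TSV dialect, and the suite then checks the published
  composition (1,269 entries; 38.21% majority baseline).
* Parsing is single-shot: a malformed response is scored as-is (zeros
  plus defect records); the harness never re-prompts, so parse failures
  remain visible in the metrics instead of being retried away.
* Reasoning quality and citation accuracy are represented only as
  proportion tables compared via z-tests; the expert annotation that
  produces them is a human protocol outside this package.

## A worked example

```{r example, eval = FALSE}
corpus <- generate_corpus(corpus_params(n = 300, seed = 1))
backend <- mock_backend(responder_params(conf_range = c(0.2, 1), seed = 2))
grid <- run_grid(corpus, run_config(
  backend = backend, strategies = c("ZS", "SC"),
  n_perm = 199, n_boot = 199, seed = 3
))
glance(grid)
autoplot(grid$cells$ZS$eval) # reliability diagram
```
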