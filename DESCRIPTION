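Package: sozloc
Title: Evaluate Likelihood-Eliciting Language Responders for Seizure
    Onset Zone Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evaluation harness for probabilistic seizure onset zone
    (SOZ) localization from free-text seizure semiology. A responder (a
    large language model backend, or the package's fully offline mock) is
    asked to return a JSON dictionary of likelihoods over seven canonical
    brain regions; the package builds prompts under five strategies
    (zero-shot, few-shot, chain-of-thought, few-shot chain-of-thought,
    self-consistency), parses and validates the structured output in four
    languages, aggregates self-consistency chains by median-based majority
    voting, and scores correctness (weighted F1), confidence (normalized
    Shannon entropy), and calibration (reliability bins, Brier score) with
    bootstrap confidence intervals, permutation-based significance tests,
    and drivers for description-length, persona, and language ablations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
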