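# Expert reasoning texts attached to few-shot chain-of-thought exemplars,
# one per line, cycled over the selected exemplars. The shipped lines are
# clearly marked placeholders: replace them with reasoning written by a
# clinical expert for your own exemplar set.
[PLACEHOLDER expert reasoning 1] Identify the cardinal sign in the description, relate it to the cortical network that typically generates it, and weigh competing regions before committing likelihoods.
[PLACEHOLDER expert reasoning 2] Consider lateralizing and localizing value of each sign, check for signs that co-occur across regions, and distribute likelihood mass accordingly.
[PLACEHOLDER expert reasoning 3] Match the temporal evolution of the semiology to known propagation patterns and assign the highest likelihood to the most plausible onset region.
[PLACEHOLDER expert reasoning 4] Contrast mesial versus lateral onset patterns suggested by the signs and adjust the regional likelihoods for typical mimics.
[PLACEHOLDER expert reasoning 5] Summarize the strongest evidence, name the runner-up region, and justify the final likelihood ranking.
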