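Solve the problem in step by step manner. Include the keys "Reasoning" and "Sources" in the JSON dictionary, giving your step-by-step reasoning and the literature sources you relied on.
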