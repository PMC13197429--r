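# one stop term per line; removed as whole words, case-insensitive
patient
patients
reported
reportedly
described
presence
presented
episode
episodes
ictal
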