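Given a description of seizure symptoms (a semiology), estimate the likelihood that the seizure onset zone lies in each of the following seven brain regions: {regions}. Respond only with a JSON dictionary in which each of these seven region names is a key and the value is the likelihood in percent.
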