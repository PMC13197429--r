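请逐步解决该问题。在 JSON 字典中包含 "Reasoning" 和 "Sources" 两个键，分别给出您的逐步推理过程以及所依据的文献来源。
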