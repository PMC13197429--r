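Resuelva el problema paso a paso. Incluya las claves "Reasoning" y "Sources" en el diccionario JSON, indicando su razonamiento paso a paso y las fuentes bibliográficas utilizadas.
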