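Résolvez le problème étape par étape. Incluez les clés "Reasoning" et "Sources" dans le dictionnaire JSON, en donnant votre raisonnement étape par étape et les sources bibliographiques utilisées.
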