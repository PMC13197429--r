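À partir d'une description des symptômes d'une crise (une sémiologie), estimez la probabilité que la zone de départ de la crise se situe dans chacune des sept régions cérébrales suivantes : {regions}. Répondez uniquement par un dictionnaire JSON dont chacune de ces sept régions est une clé et dont la valeur est la probabilité en pourcentage.
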