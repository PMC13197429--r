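A partir de una descripción de los síntomas de una crisis epiléptica (una semiología), estime la probabilidad de que la zona de inicio de la crisis se encuentre en cada una de las siguientes siete regiones cerebrales: {regions}. Responda únicamente con un diccionario JSON en el que cada una de estas siete regiones sea una clave y el valor sea la probabilidad en porcentaje.
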