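language	surface	canonical
en	Temporal Lobe	Temporal Lobe
en	Frontal Lobe	Frontal Lobe
en	Cingulate Gyrus	Cingulate Gyrus
en	Cingulate Cortex	Cingulate Gyrus
en	Parietal Lobe	Parietal Lobe
en	Occipital Lobe	Occipital Lobe
en	Insula	Insula
en	Insular Cortex	Insula
en	Hypothalamus	Hypothalamus
fr	Lobe temporal	Temporal Lobe
fr	Lobe frontal	Frontal Lobe
fr	Gyrus cingulaire	Cingulate Gyrus
fr	Cortex cingulaire	Cingulate Gyrus
fr	Lobe pariétal	Parietal Lobe
fr	Lobe occipital	Occipital Lobe
fr	Insula	Insula
fr	Cortex insulaire	Insula
fr	Hypothalamus	Hypothalamus
es	Lóbulo temporal	Temporal Lobe
es	Lóbulo frontal	Frontal Lobe
es	Giro cingulado	Cingulate Gyrus
es	Circunvolución cingulada	Cingulate Gyrus
es	Lóbulo parietal	Parietal Lobe
es	Lóbulo occipital	Occipital Lobe
es	Ínsula	Insula
es	Corteza insular	Insula
es	Hipotálamo	Hypothalamus
zh	颞叶	Temporal Lobe
zh	额叶	Frontal Lobe
zh	扣带回	Cingulate Gyrus
zh	顶叶	Parietal Lobe
zh	枕叶	Occipital Lobe
zh	岛叶	Insula
zh	脑岛	Insula
zh	下丘脑	Hypothalamus
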