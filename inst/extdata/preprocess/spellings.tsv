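from	to
automatisims	automatisms
autonomatisms	automatisms
dejavu	deja vu
deja-vu	deja vu
epigastic	epigastric
siezure	seizure
seziure	seizure
tonic clonic	tonic-clonic
versive	versive
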