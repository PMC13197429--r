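from	to
LOC	loss of consciousness
GTC	generalized tonic-clonic
GTCS	generalized tonic-clonic seizure
FBTC	focal to bilateral tonic-clonic
CPS	complex partial seizure
SPS	simple partial seizure
EEG	electroencephalogram
L	left
R	right
UL	upper limb
LL	lower limb
b/l	bilateral
w/	with
w/o	without
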