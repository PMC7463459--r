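ref_a	ref_b
PYE	UNE12
PYE	AtbHLH104
PYE	ILR3
PYE	FMA
PYE	MUTE
PYE	SPCH
ICE1	FMA
ICE1	SPCH
ICE1	MUTE
HEC2	SPT
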