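name	pattern	class
G-box	CACGTG	light
ABRE	ACGTG	hormone
CGTCA-motif	CGTCA	hormone
TGACG-motif	TGACG	hormone
ERE	ATTTCAAA	hormone
MBS	CAACTG	stress
LTR	CCGAAA	stress
ARE	AAACCA	development
CAT-box	GCCACT	development
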