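gene	NFRI3236	S288C	NFRI3155
FMP21	3.68	2.18	1.35
YER034W	3.10	1.51	0.49
PRM5	48.21	23.05	15.07
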