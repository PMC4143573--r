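gene	strain	ratio
FMP21	NFRI3236	8.50
FMP21	S288C	4.50
FMP21	NFRI3155	3.47
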