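strain	temperature	td_h
NFRI3236	30C	1.15
NFRI3155	30C	1.28
S288C	30C	1.34
NFRI3236	39C	1.75
NFRI3155	39C	2.90
S288C	39C	2.11
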