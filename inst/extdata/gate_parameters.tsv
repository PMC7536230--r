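promoter	binding_constant_e3	cooperativity
AmeR	0.55	1.1
AmtR	2.24	2.4
BetI	0.12	1.7
BM3R1	0.43	1.3
HlyIIR	9.80	1.7
PhlF	0.50	4.2
SrpR	0.06	1.2
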