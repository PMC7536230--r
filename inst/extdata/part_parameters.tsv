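part	class	parameter	value	units
AmeR	promoter	y_max_e3_per_dna	67	RNAP/s per DNA x 1e-3
AmeR	promoter	y_min_e3_per_dna	0.3188	RNAP/s per DNA x 1e-3
AmtR	promoter	y_max_e3_per_dna	7.4	RNAP/s per DNA x 1e-3
AmtR	promoter	y_min_e3_per_dna	0.0002	RNAP/s per DNA x 1e-3
BAD1	promoter	y_max_e3_per_dna	4.8	RNAP/s per DNA x 1e-3
BAD1	promoter	y_min_e3_per_dna	0.0002	RNAP/s per DNA x 1e-3
BAD2	promoter	y_max_e3_per_dna	6.0	RNAP/s per DNA x 1e-3
BAD2	promoter	y_min_e3_per_dna	0.0004	RNAP/s per DNA x 1e-3
BetI	promoter	y_max_e3_per_dna	7.5	RNAP/s per DNA x 1e-3
BetI	promoter	y_min_e3_per_dna	0.0152	RNAP/s per DNA x 1e-3
BM3R1	promoter	y_max_e3_per_dna	9.3	RNAP/s per DNA x 1e-3
BM3R1	promoter	y_min_e3_per_dna	0.0235	RNAP/s per DNA x 1e-3
HlyIIR	promoter	y_max_e3_per_dna	49	RNAP/s per DNA x 1e-3
HlyIIR	promoter	y_min_e3_per_dna	0.0133	RNAP/s per DNA x 1e-3
PhlF	promoter	y_max_e3_per_dna	0.8	RNAP/s per DNA x 1e-3
PhlF	promoter	y_min_e3_per_dna	0.0002	RNAP/s per DNA x 1e-3
SrpR	promoter	y_max_e3_per_dna	0.9	RNAP/s per DNA x 1e-3
SrpR	promoter	y_min_e3_per_dna	0.0002	RNAP/s per DNA x 1e-3
Tac	promoter	y_max_e3_per_dna	4.9	RNAP/s per DNA x 1e-3
Tac	promoter	y_min_e3_per_dna	0.0002	RNAP/s per DNA x 1e-3
Tet1	promoter	y_max_e3_per_dna	171	RNAP/s per DNA x 1e-3
Tet1	promoter	y_min_e3_per_dna	0.0030	RNAP/s per DNA x 1e-3
Tet2	promoter	y_max_e3_per_dna	109	RNAP/s per DNA x 1e-3
Tet2	promoter	y_min_e3_per_dna	0.0002	RNAP/s per DNA x 1e-3
ECK120029600	terminator	strength	689	fold
ECK120033736	terminator	strength	20	fold
ECK120033737	terminator	strength	124	fold
L3S2P11	terminator	strength	15	fold
L3S2P21	terminator	strength	565	fold
L3S2P55	terminator	strength	29	fold
L3S3P11	terminator	strength	296	fold
L3S3P31	terminator	strength	136	fold
bydvJ	ribozyme	cleavage_efficiency	0.90	fraction
riboJ	ribozyme	cleavage_efficiency	0.89	fraction
riboJ10	ribozyme	cleavage_efficiency	0.87	fraction
riboJ51	ribozyme	cleavage_efficiency	0.85	fraction
riboJ53	ribozyme	cleavage_efficiency	0.91	fraction
riboJ54	ribozyme	cleavage_efficiency	0.84	fraction
riboJ57	ribozyme	cleavage_efficiency	0.48	fraction
sarJ	ribozyme	cleavage_efficiency	0.94	fraction
A1	rbs	translation_efficiency	0.85	protein/s per mRNA
B2	rbs	translation_efficiency	0.57	protein/s per mRNA
BBa_B0064	rbs	translation_efficiency	1.22	protein/s per mRNA
E1	rbs	translation_efficiency	0.04	protein/s per mRNA
F1	rbs	translation_efficiency	0.16	protein/s per mRNA
H1	rbs	translation_efficiency	14.5	protein/s per mRNA
P3	rbs	translation_efficiency	0.43	protein/s per mRNA
S2	rbs	translation_efficiency	0.07	protein/s per mRNA
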