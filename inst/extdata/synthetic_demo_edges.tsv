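gene_a	gene_b	C_used
BAK1	BCL2	0.696
BAK1	E2F1	0.712
BCL2	E2F1	0.954
E2F1	MCL1	0.684
BAK1	E2F2	0.701
E2F2	PIK3R5	0.778
BAK1	PIK3R5	0.913
BAD	PIK3R2	0.655
E2F1	E2F2	0.731
E2F2	MYC	0.642
E2F1	MYC	0.668
E2F2	E2F3	0.705
AKT1	E2F2	0.627
BAX	BECN1	0.895
AKT3	E2F3	0.660
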