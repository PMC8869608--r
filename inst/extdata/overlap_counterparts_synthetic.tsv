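side	id	gene_id	major	description
protein	spot163	SRPP_A	up	small rubber particle protein
protein	spot723	SRPP_B	irregular	small rubber particle protein
protein	spot730	SRPP_C	down	small rubber particle protein
protein	spot552	TUA3	down	tubulin alpha-3 chain-like protein
protein	spot554	LAP_A	irregular	latex abundant family protein
protein	spot628	LAP_A	down	latex abundant family protein
tdf	M1-A10-2	SRPP_A	up	small rubber particle protein
tdf	M12-A6-4	SRPP_B	up	small rubber particle protein
tdf	M6-A10-4	SRPP_C	up	small rubber particle protein
tdf	M6-A7-1	TUA3	up	tubulin alpha-3 chain-like protein
tdf	M8-A7-2	LAP_A	up	latex abundant family protein
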