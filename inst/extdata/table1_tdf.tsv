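category	up	down	irregular
Primary metabolism	15	12	3
Energy	8	5	7
Cell growth and division	11	5	3
Transcription and protein synthesis	41	35	20
Protein degradation and storage	18	9	7
Transporters and intracellular transport	20	18	7
Cellular structure	7	6	0
Signal transduction	12	18	12
Stress and defense	23	16	7
Secondary metabolism	8	2	1
Rubber biosynthesis	9	0	1
Unclassified proteins	7	16	7
Predicted proteins	24	20	15
No hit sequence	14	18	18
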