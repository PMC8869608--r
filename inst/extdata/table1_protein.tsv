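category	up	down	irregular
Primary metabolism and energy	8	5	5
Cell growth, division and structure	4	3	5
Transcription and protein synthesis	5	3	1
Signal transduction	4	0	0
Stress and defense	4	4	15
Secondary metabolism	3	1	0
Rubber biosynthesis	3	2	3
Unclassified proteins	4	2	5
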