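tdf_id	annotation	pathway	model	flag
M3-A8-4	pyruvate dehydrogenase, putative	Primary metabolism	Irregular	-
M4-A5-5	NADP-dependent glyceraldehyde-3-phosphate dehydrogenase, putative	Primary metabolism	Irregular	+
M5-A5-1	G6PD1 (glucose-6-phosphate dehydrogenase)	Primary metabolism	Irregular	+
M12-A7-2	Phosphofructokinase, putative	Primary metabolism	Irregular	+
M13-A8-2	pyruvate dehydrogenase, putative	Primary metabolism	Up	+
M13-A11-4	mitochondrial pyruvate dehydrogenase kinase isoform 2	Primary metabolism	Down	+
M13-A11-5	pyruvate kinase, putative	Primary metabolism	Up	+
M14-A7-4	Fructokinase, putative	Primary metabolism	Up	+
M15-A8-3	glyceraldehyde-3-phosphate dehydrogenase	Primary metabolism	Up	+
M16-A7-1	neutral/alkaline invertase	Primary metabolism	Up	-
M1-A6-7	cis-prenyltransferase	Rubber biosynthesis and regulation	Up	+
M1-A10-2	small rubber particle protein	Rubber biosynthesis and regulation	Up	+
M2-A10-1	rubber elongation factor	Rubber biosynthesis and regulation	Up	+
M8-A5-6	inorganic pyrophosphatase, putative	Rubber biosynthesis and regulation	Irregular	+
M11-A5-4	farnesyl diphosphate synthase	Rubber biosynthesis and regulation	Up	-
M12-A6-4	small rubber particle protein	Rubber biosynthesis and regulation	Up	+
M12-A9-3	3-hydroxy-3-methylglutaryl-coenzyme A reductase 2	Rubber biosynthesis and regulation	Up	+
M13-A5-1	rubber elongation factor	Rubber biosynthesis and regulation	Up	+
M14-A5-4	rubber elongation factor	Rubber biosynthesis and regulation	Up	+
M16-A5-4	hydroxymethylglutaryl coenzyme A synthase	Rubber biosynthesis and regulation	Up	+
M2-A6-2	AGD13 (ARF-GAP domain 13); ARF GTPase activator/zinc ion binding	Transporters and intracellular transport	Irregular	+
M2-A7-5	vacuolar ATP synthase subunit G plant, putative	Transporters and intracellular transport	Up	+
M3-A12-1	RAB6A; GTP binding/protein binding	Transporters and intracellular transport	Irregular	+
M4-A6-5	small Ras-like GTP-binding protein	Transporters and intracellular transport	Down	+
M9-A9-1	AtRABA1f (Arabidopsis Rab GTPase homolog A1f); GTP binding	Transporters and intracellular transport	Up	+
M10-A8-1	sugar transporter, putative	Transporters and intracellular transport	Up	+
M11-A7-1	vacuolar ATP synthase proteolipid subunit 1, 2, 3, putative	Transporters and intracellular transport	Up	+
M13-A7-7	prenylated Rab acceptor protein, putative	Transporters and intracellular transport	Down	+
M15-A6-6	AtRABH1e (Arabidopsis Rab GTPase homolog H1e); GTP binding	Transporters and intracellular transport	Up	+
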