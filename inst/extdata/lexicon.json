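{
  "Rubber biosynthesis": [
    "rubber elongation factor", "small rubber particle", "cis-prenyltransferase",
    "farnesyl diphosphate synthase", "hydroxymethylglutaryl",
    "3-hydroxy-3-methylglutaryl", "inorganic pyrophosphatase",
    "acetyl-coa c-acetyltransferase"
  ],
  "Transporters and intracellular transport": [
    "transporter", "vacuolar atp synthase", "rab gtpase", "ras-like gtp-binding",
    "arf-gap", "rab acceptor", "rab6a", "aquaporin", "clathrin", "coatomer"
  ],
  "Primary metabolism": [
    "pyruvate dehydrogenase", "pyruvate kinase", "fructokinase",
    "phosphofructokinase", "glyceraldehyde-3-phosphate dehydrogenase",
    "glucose-6-phosphate dehydrogenase", "invertase", "sucrose synthase",
    "enolase", "aldolase", "triosephosphate isomerase", "malate dehydrogenase"
  ],
  "Secondary metabolism": [
    "chalcone", "flavonoid", "terpene synthase", "phenylalanine ammonia-lyase",
    "cytochrome p450", "polyphenol oxidase"
  ],
  "Energy": [
    "atp synthase", "cytochrome c oxidase", "nadh dehydrogenase", "photosystem",
    "ferredoxin", "adenylate kinase"
  ],
  "Cell growth and division": [
    "cyclin", "cell division", "histone", "dna replication", "expansin"
  ],
  "Transcription and protein synthesis": [
    "ribosomal protein", "transcription factor", "rna polymerase",
    "translation initiation", "elongation factor 1", "elongation factor 2",
    "trna synthetase", "rna-binding", "zinc finger"
  ],
  "Protein degradation and storage": [
    "proteasome", "ubiquitin", "protease", "peptidase", "storage protein",
    "cysteine proteinase"
  ],
  "Cellular structure": [
    "tubulin", "actin", "microtubule", "cellulose synthase", "profilin"
  ],
  "Signal transduction": [
    "protein kinase", "calmodulin", "phosphatase 2c", "receptor kinase",
    "14-3-3", "calcium-binding"
  ],
  "Stress and defense": [
    "heat shock", "chitinase", "glucanase", "pathogenesis-related", "peroxidase",
    "glutathione", "superoxide dismutase", "latex abundant", "hevein",
    "thioredoxin"
  ]
}
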