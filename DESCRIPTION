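Package: tapseq
Title: Tapping-Series Expression Analysis for Hevea Latex Transcripts and Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of transcript and protein abundance across five
    successive tappings of rubber trees (Hevea brasiliensis). Normalizes
    gel-band and spot-volume intensity series to the first tapping,
    classifies trajectories into up-, down- and irregular-regulation
    subtypes, calls differential expression by across-tapping ANOVA or a
    fold-change plus t-test rule, removes redundant transcript-derived
    fragments, triages BLAST annotations into functional categories,
    quantifies qRT-PCR data by the 2^-ddCt method, and scores concordance
    between platforms. Includes a synthetic-data generator reproducing the
    statistical structure of the assays so the whole pipeline is testable
    without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    seqinr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
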