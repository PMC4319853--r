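Package: pomiR
Title: Small RNA Sequencing Analysis of Tree Peony miRNAs Under Copper Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA-seq tag analysis pipeline for plants
    without a reference genome, modelled on the Paeonia ostii copper-stress
    study design (a control and a treated library). Covers adaptor trimming
    and tag collapsing, transcriptome mapping and ncRNA classification,
    conserved miRNA identification through a temporary-database procedure,
    novel miRNA (hairpin) discovery with an embedded nearest-neighbor RNA
    folding engine, isomiR cataloguing, rule-based miRNA target prediction
    with G:U wobble scoring, and Audic-Claverie differential expression of
    tag counts between two libraries. A seeded synthetic-data generator with
    a ground-truth manifest makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
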