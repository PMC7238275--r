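Package: podmat
Title: Pod-Maturation Transcriptome Inference for Common Bean
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a transcriptome-inference pipeline
    for identifying pod-maturation genes in common bean (Phaseolus vulgaris).
    Provides replicate-concordance quality control by UPGMA clustering of
    top-expressed genes, all-pairwise fold-change classification of genes
    differentially expressed between immature and mature pod stages,
    cross-genotype intersection of calls, direction-concordant comparison
    against a reference species' maturation gene lists, promoter extraction
    and position-weight-matrix scanning with exact score-distribution
    p-values, transcription-factor binding-site and term over-representation
    statistics, correspondence-analysis ordination, and a fully specified
    synthetic-data generator with a ground-truth manifest for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
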