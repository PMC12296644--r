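Package: h4k20dyn
Title: Integrative Analysis of H4K20 Methylation and Pol II Occupancy
    Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of histone H4 lysine-20 methylation (H4K20me1,
    H4K20me3) and RNA polymerase II occupancy dynamics across erythroid
    maturation timepoints. Provides coverage-track input/output with RPKM
    normalisation and replicate merging, region scoring over promoters,
    gene bodies and merged exons, metagene matrices, threshold peak
    calling from bedGraph signal, genomic annotation with
    observed/expected enrichment, pausing-index classification with Welch
    comparisons, a negative-binomial Wald test for differential
    occupancy, methylation fate mapping between marks, a ground-truth
    synthetic data generator, and a configuration-driven pipeline.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
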