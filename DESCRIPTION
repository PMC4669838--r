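Package: mbdpipe
Title: MBD-Seq Differential Methylation Analysis with Lineage Preservation and qPCR Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for methyl-CpG-binding-domain capture
    sequencing (MBD-seq) differential methylation analysis: PCR-duplicate
    removal, binned coverage, Poisson peak calling of the captured fraction
    against a matched supernatant background, partition of peak sets between
    conditions into unique (DMR) and common peaks, genomic-context annotation
    against refFlat gene models and CpG islands, cross-passage peak
    preservation with a chi-square test of proportions, and qPCR relative
    expression (delta-delta-Ct) with methylation-expression concordance
    reporting. Ships a synthetic-data generator that emulates a two-condition
    (control versus dexamethasone), two-passage (parent P1, daughter D3)
    neural-stem-cell study design, with ground-truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
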