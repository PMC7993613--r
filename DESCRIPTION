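Package: bsamap
Title: Bulked-Segregant Mapping of Recessive Loci from Pooled Sequencing
Version: 0.1.0
Authors@R: person("bsamap", "maintainers", email = "bsamap@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping a recessive Mendelian locus in an F2
    intercross by bulked-segregant analysis of pooled whole-genome
    sequencing. Implements per-SNP allele-frequency differentiation (dAF)
    and pooled-heterozygosity (Hp) sliding-window scans with empirical
    top-fraction interval calling, a candidate-variant prioritization
    cascade (depth cap, quality, impact class, dAF, reference-panel
    absence), cryptic splice-donor scanning with intron-retention isoform
    construction and peptide-level consequence prediction, and
    barcode-demultiplexed long-read isoform quantification. A synthetic
    F2 cross-and-sequencing generator reproduces the statistical
    structure the analysis assumes so the full pipeline is testable with
    no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
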