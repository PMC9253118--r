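Package: thermomem
Title: Thermomemory Transcriptomics: Comparative-Ct Profiling, Interaction-Contrast
    Differential Expression, Promoter-Target Mapping and Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of the transcriptomic inference chain used
    to dissect heat-stress memory (thermomemory) in Arabidopsis: comparative-Ct
    (delta-Ct) quantification of qRT-PCR transcription-factor panels with 1.5-fold
    differential-expression calling and k-means trajectory clustering;
    precision-weighted log-CPM transformation with quantile normalization,
    per-gene weighted linear models, empirical-Bayes variance moderation,
    second-order heat-by-genotype interaction contrasts and global
    Benjamini-Hochberg decisions; strand-aware nearest-TSS assignment of DAP-seq
    binding peaks and the 1-kb upstream promoter rule; overexpressor/knockout
    direction-discordance filtering with a two-of-three timepoint commonality
    rule for candidate direct targets; weighted gene co-expression networks
    (soft-thresholding power scan, topological overlap, module detection) with
    hypergeometric target enrichment; and the chlorophyll/fresh-mass phenotype
    quantifications. A synthetic-data generator with recorded planted truth makes
    every stage verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    limma,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
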