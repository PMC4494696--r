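Package: tagdge
Title: Digital Gene Expression Tag Profiling for Sorted Cell Fractions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for 21-bp digital gene expression (DGE) tag profiling of
    the NlaIII/MmeI type: virtual restriction digestion of reference
    sequence sets into theoretical CATG-anchored tags, exact and
    mismatch-tolerant tag mapping with 3'-most tag resolution,
    counts-per-million normalisation and an exact binomial test for
    between-library comparisons, randomization-based calibration of the
    tag-occurrence noise cutoff, library saturation curves, two-tailed
    hypergeometric gene ontology enrichment with ancestor propagation, and
    3'-UTR tag-proximity profiles on a genome. A synthetic-data generator
    produces reference transcriptomes, genomes and tag libraries with known
    ground truth so that the whole pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    data.table,
    yaml,
    ggplot2,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
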