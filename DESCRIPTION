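Package: chimloci
Title: Chimeric Read Analysis for RNA-RNA Interactome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns (possibly multi-mapped) chimeric alignments from RNA-RNA
    interactome and structurome experiments (CLASH, CLEAR-CLIP, PARIS, SPLASH)
    into quantified, annotated, probabilistically scored RNA-RNA interactions.
    Reads are UMI-deduplicated, alignments are merged into expressed loci,
    loci sharing multi-mapped read segments are grouped into common read loci
    (CRLs) by Jaccard single-linkage clustering, CRL abundances are estimated
    by expectation-maximization, and the two most probable chimeric arms per
    read are extracted, annotated and scored. A benchmark simulator generates
    fused miRNA-like/target-like chimeric reads over paralogous references
    with per-read ground truth, and an evaluator assigns pipeline output to
    seven alignment-quality categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicAlignments,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
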