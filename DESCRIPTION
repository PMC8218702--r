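Package: sorfkit
Title: Harmonization of Heterogeneous Short Open Reading Frame Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a non-redundant, uniformly annotated repository of short
    open reading frames (sORFs) from heterogeneous per-source catalogs:
    per-source quality control on theoretical ORF lengths, genome-build
    homogenization through chain-file liftover with strict failure criteria,
    two-phase merging of redundant entries into unique ORFs with experiment
    counts, transcript attachment with transcript-relative coordinates,
    normalized ORF classification (uORF, dORF, overlapping, ncRNA, NMD, NSD),
    Kozak context calling, and hypergeometric over-representation analysis of
    uORF-harboring gene sets with Benjamini-Hochberg correction. Ships a
    deterministic synthetic-fixture generator (toy genomes, annotations,
    chain files, redundant multi-source catalogs with a ground-truth
    manifest) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
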