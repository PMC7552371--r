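Package: annocure
Title: Comparative-Genomic Screens and Curation for Gene Annotations
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control and bulk curation of draft gene annotations.
    Implements comparative-genomic screens for suspicious gene models in a
    focal genome: protein length-ratio comparison of one-to-one orthologs,
    detection of atypical protein domain combinations absent from reference
    species, length-outlier detection within large Pfam-defined gene
    families, and identification and strand-aware classification of
    species-specific orphan genes (SSOGs). A curation engine applies
    keep/remove/replace-with-transcripts decisions in bulk, rewrites the
    annotation as GFF3, and recomputes comparative statistics including a
    read-assignability metric. A synthetic-fixture generator plants known
    defects (artificial gene fusions, antisense orphan models, atypical
    domain pairs) so every screen is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
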