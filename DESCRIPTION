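Package: dbdthreadr
Title: DNA-Binding Domain Characterization and Contact-Restricted Genome Threading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes putative DNA-binding domains on an apo protein
    from protein-dsDNA complex structures and identifies compatible genomic
    binding targets. Detects and classifies protein-DNA heavy-atom contacts
    (backbone versus side chain), chains short dsDNA backbone fragments into
    extended fragments, derives lowest-free-energy consensus binding
    sequences from per-position per-nucleotide delta-delta-G mutational-scan
    energy matrices, threads gene sequences on both strands restricted to
    contact positions, and ranks genes by binding-site density normalized by
    gene length. Ships a synthetic-data generator (complex structures,
    energy files, gene sets with planted sites) with ground-truth manifests
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    bio3d,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
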