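Package: famscan
Title: Genome-Wide Characterization of UDP-Glycosyltransferase Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies members of the plant UDP-glycosyltransferase (UGT)
    family by scanning proteins for the 44-residue PSPG (plant secondary
    product glycosyltransferase) box with a position-specific log-odds model,
    computes per-protein statistics (length, average molecular weight,
    isoelectric point by bisection on the Bjellqvist pKa set), extracts
    introns from gene models with codon phases, projects intron positions
    through a protein multiple sequence alignment and numbers homologous
    insertion events, builds neighbor-joining trees from p-distances with
    reference-guided phylogenetic group assignment, and profiles expression
    as RPKM with tissue-detection Venn partitions and z-scored hierarchical
    clustering. A seeded simulator generates genomes, gene models, true
    alignments and count tables with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    scales,
    jsonlite,
    stats,
    utils,
    ape,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
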