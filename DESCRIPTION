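Package: vntrscheme
Title: Repeat-Unit Decomposition and Comparative Analysis of VNTR
    Composite Retrotransposon Central Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the central Variable Number of Tandem
    Repeats (VNTR) domain of hominoid composite retrotransposons (SVA,
    LAVA, PVA, FVA). Segments VNTR nucleotide sequences into ordered
    repeat-unit (RU) schemata by optimal dynamic-programming tiling
    against a coded RU alphabet, discovers RU consensus sequences from
    pre-split units by length sorting and majority rule, derives
    subfamily-specific conserved 5'/3' RU arrays and internal repeated
    motifs, and compares orthologous elements to call RU copy-number
    indels, measure breakpoint microhomology, and label compatibility
    with slippage, NAHR and MMEJ-type mechanisms. Includes a
    ground-truthed synthetic-data generator for subfamily element sets
    and ortholog pairs with planted microhomology-mediated indels.
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
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils,
    stats,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
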