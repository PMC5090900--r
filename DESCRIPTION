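Package: aartools
Title: Comparative Analysis of Cyanobacterial Acyl-ACP Reductases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for ranking cyanobacterial acyl-ACP reductase (AAR)
    orthologs from sequence and expression data: pairwise percent-identity
    matrices from affine-gap global alignments, neighbor-joining phylogenies
    with clade grouping and habitat composition summaries, soluble-protein
    normalized aldehyde-producing activity indices from hydrocarbon and
    western-blot densitometry tables, product-spectrum (chain-length)
    specificity fractions, property-versus-identity correlations with
    leave-one-out checks, and an alignment-column scan that nominates
    activity- and specificity-determining residues as single-substitution
    proposals. A synthetic-data module generates protein families with
    planted group-diagnostic residues and noisy measurement tables so every
    stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    jsonlite,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
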