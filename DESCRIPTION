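Package: trcensus
Title: Phylogenomic Census of Thioredoxin-Reductase Subfamilies
Version: 0.1.0
Authors@R: person("trcensus", "developers", role = c("aut", "cre"),
    email = "trcensus@example.org")
Description: Detects pyridine nucleotide-disulfide oxidoreductase (PNDO)
    domain proteins in proteomes with a trusted-cutoff profile search,
    groups them into thioredoxin-reductase (TR) subfamilies by
    seed-anchored protein similarity networks, extracts the fixed-width
    BoxA/BoxB active-site and NAD(P)H-binding regions, enriches each
    subfamily iteratively with a BoxB profile, splits groups by
    active-site cysteine and thioredoxin-partner rules (TR1 vs FdR, TR3
    vs dcTR1), computes sequence logos and consensus motifs, and builds
    neighbor-joining trees to flag gene-duplication and horizontal gene
    transfer candidates.  Ships a synthetic proteome generator with
    planted motif templates so the whole pipeline is testable without
    external genome databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
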