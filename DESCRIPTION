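Package: aniscreen
Title: Marker-Gene Screening and Bacterial Species Delimitation by Average Nucleotide Identity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering taxonomic marker genes whose gene-level
    average nucleotide identity (ANIg) recapitulates genome-level ANI (ANIm)
    species boundaries, and for delimiting and auditing bacterial species from
    marker-gene concatenates using inter/intra-species ANI boundaries (94%/96%).
    Includes a fragment-seeded genome ANI engine, difference-count gene ANI,
    gap and boundary-concordance screening of candidate markers, a pairwise
    94/96 classifier with type-strain panel audits and query assignment,
    correlation and curve-estimation concordance statistics, neighbor-joining
    and Robinson-Foulds congruence checks, a pairwise homoplasy (PHI)
    recombination permutation test, and a sequence-panel simulator with exact
    realized-divergence ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    broom,
    jsonlite,
    stats,
    utils,
    ape,
    phangorn,
    igraph,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
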