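Package: barbetdiv
Title: Community Phylogenetics and Trait Divergence in Sympatric Bird Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to test how sympatric assemblages of related species are
    structured phylogenetically and in trait space, developed around Asian
    barbet (Megalaimidae) communities. Converts occurrence records to
    presence-absence grids and computes the pairwise DO co-occurrence index;
    correlates co-occurrence with cophenetic distance against an
    independent-swap (checkerboard) null model; ordinates log-transformed
    morphometrics by covariance PCA via singular value decomposition;
    quantifies pairwise trait overlap with Cohen's d and community trait
    dispersion with a randomization Z-score; extracts peak frequencies from
    annotated field recordings and tests frequency partitioning within
    multi-species choruses; and estimates phylogenetic signal with Blomberg's
    K and a tip-shuffle randomization test on independent contrasts. A seeded
    synthetic-data generator (Yule trees, Brownian traits, specimen samples,
    community assembly, tonal choruses) makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    picante,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
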