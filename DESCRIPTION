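Package: nlrcensus
Title: Motif-Based Classification and Cross-Species Census of Plant NLR
    Immune Receptors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for surveying nucleotide-binding leucine-rich-repeat
    (NLR) immune receptors in predicted proteomes, with an emphasis on
    conifer transcriptomes. Classifies sequences into the CNL, CNL2, RNL
    and TNL subfamilies (plus truncated and atypical forms) from domain
    architecture and degenerate NB-ARC motif signatures (RNBS-A, RNBS-D
    and MHD variants), performs CD-HIT-style greedy identity clustering
    and redundancy removal, assigns RPW8 domains to RNL groups via
    neighbor-joining trees anchored on reference sequences, computes
    cross-species census statistics (distribution percentages,
    transcriptome ratios, chi-square homogeneity, RNL-versus-TNL
    regression), and tests drought-responsive differential expression
    with a simplified negative-binomial likelihood-ratio test followed by
    expression grouping. Seed-deterministic synthetic-data generators
    with machine-readable truth tables emulate every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
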