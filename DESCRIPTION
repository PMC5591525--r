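Package: rbpcobind
Title: Co-Binding Group Discovery from CLIP-Seq Binding Sites by Consensus KL-NMF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-protein CLIP-seq binding peaks into a unified set of
    binding sites, normalizes CLIP signal by background RNA-seq into a bounded
    occupancy matrix, soft-clusters RNA-binding proteins into co-binding groups
    by Kullback-Leibler non-negative matrix factorization with consensus-based
    rank selection (cophenetic and dispersion coefficients), associates binding
    sites to groups by an entropy-based basis-specificity score, and evaluates
    groups with permutation and Fisher enrichment statistics (protein
    association networks, known motifs, RNA half-life, exon inclusion). Includes
    a seeded synthetic-scenario generator with planted group structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), mclust, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
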