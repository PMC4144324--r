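Package: hlmkin
Title: Two-Stage Hierarchical Linear Models for Longitudinal Genetic
    Association in Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Genetic association analysis of longitudinal phenotypes
    measured in large pedigrees.  Per-individual linear age trajectories
    are fitted in a first stage, and the resulting intercepts (phenotype
    level at a reference age) and slopes (rate of change) are tested for
    single-nucleotide polymorphism effects in a second stage using
    kinship-structured linear mixed models estimated by restricted
    maximum likelihood via a single eigendecomposition of the
    relationship matrix.  Includes recursive pedigree kinship
    computation, a gene-dropping synthetic cohort generator with known
    ground truth, genomic-control diagnostics, and replicate-based power
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
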