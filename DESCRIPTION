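Package: haploscan
Title: Single-SNP Versus Haplotype-Block Genome-Wide Association in Inbred Crops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Benchmarking framework comparing single-SNP and haplotype-based
    genome-wide association analysis in inbred (haploid-coded) crop panels.
    Provides founder-mosaic genotype simulation with map-tied markers, three
    haplotype blocking methods (four-gamete, diversity-coverage dynamic
    programming, overlapping sliding windows), probabilistic haplotype
    incidence matrices, parsimony-tree edge (clade) association columns,
    an EMMA-style spectral mixed-model likelihood-ratio scan supporting
    multi-degree-of-freedom tests, QTL and polygene phenotype simulation
    with exact in-sample variance control, and power estimation at an
    empirical false discovery rate via bootstrap, together with permutation
    thresholds and effective test numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
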