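Package: cbscofactor
Title: Functional Classification and Cofactor-Remediation Analysis of CBS Variants
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single amino-acid variants of human
    cystathionine beta-synthase (CBS) assayed by functional complementation
    in yeast. Estimates exponential-phase growth rates from microplate
    OD595 time-series (endpoint normalization, log10 transform,
    fixed-density-window slopes, plate normalization), classifies variants
    as nonfunctional, cofactor-sensitive, or benign under titrated
    pyridoxine (vitamin B6) and delta-aminolevulinate (heme precursor)
    supplementation, computes five per-residue structural features from a
    PDB structure (distance to heme, distance to PLP, relative solvent
    accessibility, regular secondary structure, B-factor), tests
    phenotype-feature association by random reassignment of alleles to
    categories, and sweeps a Rosetta ddG stability threshold for
    classification accuracy. Includes seedable generators for synthetic
    growth curves, variant panels, and helical structures so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
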