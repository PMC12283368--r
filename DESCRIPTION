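Package: crcpool
Title: Pooled Multi-Cohort Analysis of Colorectal Cancer Stool Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cross-cohort computational framework for pooled analysis of
    colorectal cancer (CRC) stool metagenomes. Derives oral-typical species
    signatures from paired body-site presence data and computes oral-to-gut
    introgression scores; performs per-feature random-effects meta-analysis of
    Hedges' g standardized mean differences across cohorts with REML or
    Paule-Mandel heterogeneity estimation, Hartung-Knapp intervals and
    Benjamini-Hochberg multiplicity control; runs blocked-permutation PERMANOVA
    on Bray-Curtis or Jaccard distances; evaluates classifiers under
    per-dataset cross-validation, across-dataset transfer and
    leave-one-dataset-out designs; engineers strain-level single-nucleotide
    variant features from marker-gene alignments via entropy selection,
    one-hot encoding, prevalence and collinearity pruning; and compares
    biomarker signatures by Jaccard similarity, overlap fractions and
    covariate-adjusted partial Spearman rank scores. Ships a synthetic
    multi-cohort generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ranger,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    metafor,
    permute
Config/testthat/edition: 3
RoxygenNote: 7.3.3
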