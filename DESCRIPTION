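Package: fourlocus
Title: Four-Locus Risk-Genotype Analysis for Childhood Asthma Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for case-control association analysis of the four-SNP
    childhood-asthma gene model built on ADRB2 rs1042713, IL4 rs2243250,
    FCER1B rs569108 and IL13 rs20541. Provides gene-counting genotype and
    allele frequency estimation, Pearson chi-square and Fisher exact
    association tests, odds ratios with Woolf confidence intervals, the
    fixed sixteen-combination high/low-risk genotype classifier together
    with its data-driven derivation rule, a seeded synthetic cohort
    generator, and a pipeline that renders the standard demographic,
    per-locus and risk-distribution report tables. Ships reference
    genotype-frequency tables for Han and Kazak cohorts from Xinjiang,
    China, from which integer counts and deterministic fixture cohorts
    are reconstructed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
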