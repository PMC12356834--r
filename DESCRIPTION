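Package: cmhburden
Title: Rare-Variant Collapsing Burden Analysis with Stratified
    Cochran-Mantel-Haenszel Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-based collapsing analysis of rare, protein-altering
    variants in stratified case-control exome studies. Provides variant-
    and sample-level quality control (per-call depth and allelic-balance
    masking, Hardy-Weinberg exact test, differential-missingness filter,
    coverage, heterozygosity and singleton outlier screens, KING-robust
    relatedness, ancestry PCA on LD-pruned common variants), qualifying
    variant selection (minor allele frequency, protein-truncating classes,
    CADD score), dominant carrier collapsing into per-stratum 2x2 tables,
    Cochran-Mantel-Haenszel stratified association with Mantel-Haenszel
    common odds ratios, Robins-Breslow-Greenland confidence intervals and
    Haldane-Anscombe zero-cell correction, covariate-adjusted logistic
    burden models with a Firth fallback, secondary stratified analyses,
    analytic and simulation-based power calculations, and a synthetic
    multi-cohort exome generator so the whole pipeline is testable at desk
    scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
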