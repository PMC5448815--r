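Package: confeti
Title: Confounding Factor Estimation Through Independent Component Analysis
    for eQTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the CONFETI framework for expression quantitative
    trait locus (eQTL) mapping. Gene expression is decomposed with FastICA,
    independent components carrying genotype (candidate broad impact eQTL)
    signal are flagged by regression screening and excluded, and the sample
    covariance of the reconstructed non-genetic expression is used as the
    random-effect covariance in a linear mixed model genome-wide scan with
    Wald tests. Includes expression/genotype input with quality-control
    filters (minor allele frequency, LD pruning, skew filters, genotype
    principal components), fixed-effect baselines (simple linear regression
    and expression-PC covariates), per-gene genomic inflation diagnostics,
    Benjamini-Hochberg adjustment, cis/trans labeling, cytoband collapsing,
    pseudo-trans artifact screening, replication counting, broad impact eQTL
    detection, and a simulation benchmark with planted cis, trans and broad
    impact effects and sparse/dense confounders.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
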