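Package: csfmet
Title: Untargeted CSF Metabolomics: QC Filtering, PLS-DA Biomarker
    Discovery and Pathway Analysis
Version: 0.1.0
Authors@R:
    person("CSF Metabolomics Pipeline", "Maintainers", email = "maintainers@csfmet.dev",
           role = c("aut", "cre"))
Description: A reusable pipeline for untargeted LC-HRMS metabolomics of
    cerebrospinal fluid in case/control cohorts. Implements the full
    preprocessing cascade (blank-based contaminant removal, dilution-series
    linearity filtering, log2 transformation, TIC outlier detection,
    coverage filtering, pooled-QC LOESS drift normalization, QC coefficient
    of variation, replicate merging, albumin-ratio blood-contamination
    filtering and mean imputation), spectral-library identification with
    MS/MS validation levels, linear age detrending, two-class PLS-DA with
    VIP scoring and repeated stratified cross-validation (averaged VIPs,
    AUROCs and ROC curves, permutation tests, held-out projection),
    differential statistics (Welch tests, Benjamini-Hochberg FDR),
    hypergeometric pathway over-representation with betweenness-centrality
    impact, and Spearman association analysis against clinical and
    radiological measures. Ships a synthetic-cohort generator emulating a
    complete study design so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
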