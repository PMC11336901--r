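Package: spatialITH
Title: Spatial Intra-Tumoral Heterogeneity Analysis for Digital Spatial
    Profiling Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of GeoMx-style digital spatial profiling (DSP)
    transcriptomes from multi-region tumor sampling, motivated by small
    cell lung cancer (SCLC). Provides negative-probe limit-of-quantitation
    (LOQ) quality control, Q3 (upper-quartile) normalization, per-region
    heterogeneity scoring (DEPTH-style deviation statistic), inter-region
    concordance (C-score) against spatial physical distance, highly
    variable gene selection and Ward clustering into intra-tumoral
    heterogeneity (ITH) phenotypes, SCLC transcription-factor subtype and
    neuroendocrine (NE) score calling, patient-level sub-tumor-
    microenvironment classification with Kaplan-Meier/log-rank outcome
    statistics, one-vs-rest differential expression with Spearman
    co-expression networks and marker-module scoring, and a bootstrap
    autoencoder plus gradient-boosted-tree gene-signature classifier
    (ITHtyper) for risk stratification of region or bulk profiles. A
    synthetic-data generator with planted ground truth makes the whole
    pipeline testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    limma,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
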