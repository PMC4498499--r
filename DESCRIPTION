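Package: irongc
Title: Genetic Evaluation of Iron-Status Traits and Atherosclerosis
Version: 0.1.0
Authors@R: person("NBS", "Pipeline Maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: A tested pipeline for evaluating shared genetics between iron-status
    biomarkers (hepcidin, ferritin, serum iron, TIBC, transferrin saturation and
    the hepcidin ratios) and non-invasive measurements of atherosclerosis (carotid
    plaque, intima-media thickness, ankle-brachial index). Implements Mendelian
    randomization with single-SNP and multi-SNP allele-score models, cross-trait
    association of outcome SNPs with biomarkers, genetic relationship matrix (GRM)
    construction with LD pruning and cryptic-relatedness filtering, bivariate
    average-information REML for genomic correlations, and a Bayesian multi-trait
    latent-factor genomic model with DIC-based selection of the number of latent
    variables. Includes a synthetic-data generator with known heritabilities,
    genetic correlations and liability-threshold binary traits for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
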