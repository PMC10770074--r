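Package: mkmarker
Title: Multi-Cohort Multi-Kingdom Microbiome Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stratified multi-cohort workflow for discovering and
    validating multi-kingdom (bacterial, fungal, archaeal, viral) gut
    microbiome biomarkers of colorectal cancer. Implements prevalence and
    abundance filtering of metagenomic relative-abundance profiles,
    batch-aware per-cohort differential-abundance modelling pooled by
    inverse-variance meta-analysis, three-step marker selection (effective
    feature screening, collinear exclusion, recursive feature elimination),
    random-forest panel construction with cross-validated AUROC and
    bootstrap confidence intervals, cohort-to-cohort, leave-one-cohort-out
    and external-cohort validation, a spike-in disease-specificity
    assessment, SparCC compositional co-abundance networks with permutation
    significance, and all-against-all species-pathway association testing.
    Ships a multi-cohort synthetic-data generator with known ground truth
    so the entire pipeline is testable without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
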