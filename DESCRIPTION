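Package: glycodelta
Title: Comparative N-Glycoproteomics of Multiplexed Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of intact N-glycopeptide and protein
    quantification tables from isobaric (TMT) labeling experiments with
    paired tumor and normal-adjacent-tissue designs. Provides glycan
    composition parsing and five-class typing (high-mannose, sialylated,
    fucosylated, complex/hybrid, fucosylated-sialylated), sequon motif
    validation, reference-channel batch normalization and multi-batch
    integration without imputation, missingness filtering, protein-corrected
    differential glycopeptide classification that separates glycosylation
    occupancy changes from protein abundance changes, site
    microheterogeneity and cohort-comparison statistics, single-sample gene
    set enrichment (ssGSEA) immune scoring with correlation screens, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
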