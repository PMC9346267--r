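Package: ihcquant
Title: Digital Quantification of DAB Immunohistochemistry with
    Observer-Agreement Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Open and reproducible digital image analysis of brightfield
    H-DAB immunohistochemistry fields: optical-density stain separation into
    hematoxylin and DAB channels, nuclei detection and whole-cell
    delimitation, per-field percentage of positive cells and staining
    intensity per unit area, aggregation across fields and across independent
    selector/analyzer observer combinations, a semi-quantitative
    immunoreactivity score (IRS), and the validation-statistics layer used to
    assess such protocols: Lin's concordance correlation coefficient with
    confidence intervals and agreement categories, Spearman correlation,
    Kruskal-Wallis and one-way ANOVA group tests, and ROC analysis with
    Youden-index cut-offs and paired DeLong AUC comparison. A synthetic-data
    module generates H-DAB-like fields with ground truth, multi-observer
    measurement tables and score/outcome tables so the whole pipeline is
    testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
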