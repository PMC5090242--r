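Package: snpmetrics
Title: Performance-Metric SNP Selection and Point-Based Genetic Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-stage case-control genetic association studies that
    select single-nucleotide polymorphisms (SNPs) by diagnostic performance
    metrics rather than P-value rank. Provides PLINK text-format input,
    quality control with the Hardy-Weinberg exact test, dominant-model
    contingency tables and the ten marker performance metrics (sensitivity,
    specificity, Youden index, PPV, NPV, diagnostic odds ratio, accuracy, net
    sensitivity, net specificity, AUC), simultaneous two-marker (parallel)
    testing, conditional and unconditional logistic modelling, point-based
    risk-score derivation from logistic coefficients with risk grouping, and
    leave-one-out cross-validated optimism correction of the AUC. A synthetic
    two-stage case-control study generator with known ground truth supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
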