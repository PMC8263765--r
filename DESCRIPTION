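Package: cmdx
Title: Cumulative-Methylation Diagnostics for Lymph-Node Fine-Needle Aspirates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for an automated methylation-specific qPCR assay
    that detects breast-cancer metastasis in lymph-node fine-needle aspirates.
    Fits per-gene standard curves relating delta-Ct to the methylated-DNA
    fraction, converts raw Ct panels into per-gene percent methylation and a
    10-gene cumulative methylation (CM) score, classifies samples against a CM
    threshold, and evaluates diagnostic accuracy (sensitivity, specificity,
    PPV, NPV with exact confidence intervals; ROC-AUC with DeLong intervals)
    against histology or cytology. Includes subgroup statistics, the study's
    sample-size design computations, and a seeded synthetic-cohort generator
    emulating the study's data structure so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
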