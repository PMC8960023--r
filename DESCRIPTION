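Package: pathrex
Title: Rule-Based Extraction of Prognostic Parameters from Free-Text
    Breast-Cancer Pathology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns free-text narrative breast-cancer pathology reports into
    analysis-ready structured data using a multi-pass, regular-expression
    extraction cascade. Covers SNOMED morphology/behaviour retrieval of
    malignant cases, keyword-window summarisation and value capture for
    hormone receptors (Allred scores), HER2, Ki67 proliferation index,
    Nottingham grade, laterality and histologic type, harmonisation into
    molecular subtypes (Luminal A/B, HER2-overexpressing, triple negative),
    validation via Cohen's kappa, precision/recall/F1 and intraclass
    correlation, iterative random-forest imputation of mixed-type
    missingness, and univariable multinomial/binary logistic association
    analysis with Wald intervals. Ships a synthetic report generator that
    emulates real-world reporting heterogeneity with known ground truth, so
    the full pipeline is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
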