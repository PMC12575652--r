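Package: multipgs
Title: Multi-Polygenic-Score Risk Prediction for Colorectal Neoplasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and validates composite multiple polygenic scores (MPS)
    for colorectal-cancer risk prediction. Parses PGS-Catalog-format scoring
    files and applies a four-stage exclusion cascade; computes per-individual
    polygenic risk scores from genotype dosages with allele-orientation
    handling and mean imputation; estimates confounder-adjusted AUC by case
    reweighting with bootstrap standard errors and paired z-tests on AUC
    differences; selects predictive non-CRC scores by elastic-net logistic
    regression with unpenalized covariates tuned by cross-validated adjusted
    AUC; fits nested logistic risk models for advanced neoplasia; and
    simulates liability-threshold case-control cohorts with pleiotropic
    secondary traits so the whole pipeline runs on synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
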