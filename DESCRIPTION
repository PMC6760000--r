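Package: gaitdti
Title: Predicting Toddler Gait Impairment from Neonatal Brain DTI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive three-feature subset selection over regional neonatal
    diffusion-tensor-imaging (DTI) scalars, scored by leave-one-out
    cross-validated L2-penalized linear and logistic regression, to predict
    continuous and binarized toddler gait outcomes (velocity, step length,
    step width, single-limb support, and a temporal-spatial deviation index).
    Includes covariate residualization for postmenstrual age at scan,
    normative-threshold impairment labeling, ROC construction with a balanced
    operating point maximizing sensitivity^2 + specificity^2, a structural-MRI
    comparison arm, a tensor-eigenvalue-based synthetic cohort generator with
    planted signals for end-to-end validation, and permutation-null
    diagnostics for selection bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
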