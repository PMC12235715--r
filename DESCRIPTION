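Package: gestprot
Title: Longitudinal Maternal Plasma Proteomics of Fetal Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal maternal plasma proteomics
    across gestation in relation to birth-weight groups (small, adequate and
    large for gestational age). Provides winsorization and gestational-age
    detrending of protein abundances to multiples-of-the-mean (MoM) values
    against reference curves fitted on adequate-for-gestational-age samples,
    empirical-Bayes moderated t-tests for differential abundance and
    birth-weight z-score association, leakage-free leave-one-out
    cross-validated prediction of birth-weight group with within-fold feature
    screening (elastic net and random forest), hypergeometric
    over-representation analysis with Jaccard-based redundancy reduction,
    per-group longitudinal trajectory fits, exact clinical group comparisons
    (Welch t, Fisher r x c enumeration, Spearman), and a synthetic cohort
    generator emulating the three-visit study design for fully reproducible
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    glmnet,
    randomForest,
    ape,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    jsonlite
Config/testthat/edition: 3
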