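Package: rlddm
Title: Hybrid Reinforcement-Learning Drift-Diffusion Modelling of Probabilistic Reversal Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-based fitting of a hybrid
    reinforcement-learning drift-diffusion model (RLDDM) for two-alternative
    probabilistic reversal learning under a response deadline. Provides a
    synthetic-cohort generator with known ground truth, a Navarro-Fuss Wiener
    first-passage-time likelihood with maximum a posteriori fitting, parameter
    recovery and predictive/generative model validation, construction of
    integrated-evidence parametric regressors for model-based fMRI first-level
    designs (double-gamma HRF, synthetic BOLD, OLS beta recovery), and the
    accompanying statistical layer: percentage-bend robust correlation,
    Benjamini-Hochberg adjustment, ANCOVA group contrasts, cross-validated
    AUC-ROC classification with a permutation null, and noncentral-t power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
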