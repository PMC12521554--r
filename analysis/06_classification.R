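#!/usr/bin/env Rscript
# Stage 6: out-of-sample classification of treatment response.
#
# 5-fold cross-validated linear classification of responder status from the
# estimated EA betas, scored by trapezoidal AUC-ROC with a 100-permutation
# null on the pooled decision values.

suppressPackageStartupMessages(library(rlddm))

seed <- 1
out <- "results"
clin <- read_clinical(file.path(out, "clinical.csv"))
ea <- read.csv(file.path(out, "ea_betas.csv"))

feats <- cbind(ea_beta = ea$ea_beta_hat)
cv <- cv_classify_auc(feats, clin$group, k = 5, seed = seed + 907L)
perm <- permutation_pvalue(feats, clin$group, cv$auc, n_perm = 100, k = 5,
                           seed = seed + 911L)

jsonlite::write_json(list(auc = cv$auc, p_perm = perm$p_perm,
                          n_perm = perm$n_perm),
                     file.path(out, "classification.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("AUC-ROC = %.3f, permutation p = %.3f (%d shuffles)\n",
            cv$auc, perm$p_perm, perm$n_perm))
cat("wrote classification.json\n")
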