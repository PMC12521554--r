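#!/usr/bin/env Rscript
# Stage 5: group-level statistics.
#
# ANCOVA group contrasts (response group + pre-treatment severity) on the
# behavioural parameter estimates and accuracy (expected null) and on the
# estimated EA betas (expected group difference), plus the brain-behaviour
# bend correlation with residualized post-treatment severity, BH-adjusted.

suppressPackageStartupMessages(library(rlddm))

out <- "results"
fit_tab <- read.csv(file.path(out, "fit_results.csv"))
clin <- read_clinical(file.path(out, "clinical.csv"))
ea <- read.csv(file.path(out, "ea_betas.csv"))
subjects <- read_behaviour(file.path(out, "behaviour.csv"))

stopifnot(identical(fit_tab$subject_id, clin$subject_id),
          identical(fit_tab$subject_id, ea$subject_id))
acc <- vapply(subjects, function(s) {
  tr <- s$trials
  mean(tr$accuracy[!tr$late])
}, numeric(1))

beh <- lapply(c("kappa", "a", "alpha", "ndt"), function(v)
  ancova_group_effect(fit_tab[[v]], clin$group, clin$pre_bdi))
names(beh) <- c("kappa", "a", "alpha", "ndt")
beh$accuracy <- ancova_group_effect(acc, clin$group, clin$pre_bdi)
ea_con <- ancova_group_effect(ea$ea_beta_hat, clin$group, clin$pre_bdi)

keep <- !is.na(clin$post_bdi)
res_bdi <- residuals(lm(clin$post_bdi[keep] ~ clin$pre_bdi[keep]))
bb <- percentage_bend_correlation(ea$ea_beta_hat[keep], res_bdi)

raw_p <- c(vapply(beh, `[[`, numeric(1), "p"), ea_beta = ea_con$p,
           brain_behaviour = bb$p)
report <- list(
  behavioural = lapply(beh, function(x) x[c("coefficient", "t", "p")]),
  ea_beta = ea_con[c("coefficient", "t", "p")],
  brain_behaviour = list(r = bb$r, t = bb$t, p = bb$p, n = bb$n),
  p_adjusted = as.list(bh_adjust(raw_p)))
jsonlite::write_json(report, file.path(out, "group_stats.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("behavioural ANCOVA p:",
    sprintf("%s %.3f", names(beh), vapply(beh, `[[`, numeric(1), "p")), "\n")
cat(sprintf("EA-beta group contrast: coef %.2f, t %.2f, p %.4f\n",
            ea_con$coefficient, ea_con$t, ea_con$p))
cat(sprintf("brain-behaviour bend r %.2f (p %.3f, n %d completers)\n",
            bb$r, bb$p, bb$n))
cat("wrote group_stats.json\n")
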