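#!/usr/bin/env Rscript
# Stage 3: model validation.
#
# Parameter recovery (simulate at known parameters, refit, correlate),
# predictive checks (observed vs model-implied subject means) and the
# generative check (observed vs re-simulated behaviour per choice
# category), all summarized with 10% bend correlations.

suppressPackageStartupMessages(library(rlddm))

seed <- 1
out <- "results"
subjects <- read_behaviour(file.path(out, "behaviour.csv"))
fit_tab <- read.csv(file.path(out, "fit_results.csv"))

# rebuild lightweight fit objects from the stored parameter estimates
fits <- lapply(seq_along(subjects), function(i) {
  p <- rlddm_params(fit_tab$kappa[i], fit_tab$a[i], fit_tab$alpha[i],
                    fit_tab$ndt[i])
  structure(list(params = p,
                 trajectory = drift_trajectory(subjects[[i]]$trials, p)),
            class = "fit_result")
})

rec <- parameter_recovery(30, cohort_spec(), task_config(), fit_config(),
                          seed = seed + 17L)
write.csv(rec$table, file.path(out, "recovery.csv"), row.names = FALSE)
cat("parameter recovery (10% bend r):",
    sprintf("%s %.2f", names(rec$correlations),
            vapply(rec$correlations, `[[`, numeric(1), "r")), "\n")

pc <- do.call(rbind, lapply(seq_along(subjects), function(i)
  as.data.frame(predictive_check(subjects[[i]], fits[[i]]))))
write.csv(pc, file.path(out, "predictive_check.csv"), row.names = FALSE)
cat(sprintf("predictive: accuracy r %.2f, RT r %.2f\n",
            percentage_bend_correlation(pc$obs_accuracy, pc$pred_accuracy)$r,
            percentage_bend_correlation(pc$obs_rt, pc$pred_rt)$r))

g <- generative_check(subjects, fits, task_config(), n_sims = 300,
                      seed = seed + 211L)
write.csv(g$table, file.path(out, "generative_check.csv"), row.names = FALSE)
cat("generative (observed vs simulated, 10% bend r):",
    sprintf("%s %.2f (p %.3g)", names(g$correlations),
            vapply(g$correlations, `[[`, numeric(1), "r"),
            vapply(g$correlations, `[[`, numeric(1), "p")), "\n")
cat("wrote recovery.csv, predictive_check.csv, generative_check.csv\n")
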