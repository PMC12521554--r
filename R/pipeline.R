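#' Pipeline run configuration
#'
#' Bundles the task, cohort, fitting, first-level and statistics settings
#' with one master seed. All randomness in [run_pipeline()] is derived from
#' the master seed by fixed offsets, so a configuration plus seed fully
#' determines every output.
#'
#' @param task a [task_config].
#' @param cohort a [cohort_spec].
#' @param fit a [fit_config].
#' @param glm list: `tr`, `hrf_resolution`, `noise_sd`, `ar`, and
#'   `nuisance_betas` (named betas for the non-EA columns of the synthetic
#'   first-level model).
#' @param stats list: `n_perm`, `k_folds`, `bend_beta`.
#' @param sims list of simulation sizes: `dt` (Euler step), `n_sims_area`
#'   (paths per trial for the EA regressor), `n_sims_generative`
#'   (whole-task replications per subject), `n_recovery` (recovery-study
#'   subjects; 0 skips recovery).
#' @param out_dir output directory (NULL = nothing written to disk).
#' @param seed master integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(task = task_config(), cohort = cohort_spec(),
                       fit = fit_config(),
                       glm = list(tr = 2, hrf_resolution = 0.05,
                                  noise_sd = 0.25, ar = 0.3,
                                  nuisance_betas = c(
                                    dec_visual = 2, dec_rt = 1,
                                    dec_absdq = 0.5, out_visual = 2,
                                    out_late = 1, out_rpe = 1)),
                       stats = list(n_perm = 100, k_folds = 5,
                                    bend_beta = 0.1),
                       sims = list(dt = 1e-3, n_sims_area = 300,
                                   n_sims_generative = 300,
                                   n_recovery = 0),
                       out_dir = NULL, seed = 1) {
  stopifnot(inherits(task, "task_config"), inherits(cohort, "cohort_spec"),
            inherits(fit, "fit_config"))
  structure(list(task = task, cohort = cohort, fit = fit, glm = glm,
                 stats = stats, sims = sims, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file may override any subset of the defaults; unknown keys are
#' rejected. Nested sections mirror the [run_config()] arguments
#' (`task`, `cohort`, `fit`, `glm`, `stats`, `sims`, `out_dir`, `seed`).
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("task", "cohort", "fit", "glm", "stats", "sims", "out_dir",
             "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merge_section <- function(builder, overrides) {
    if (is.null(overrides)) return(builder())
    bad <- setdiff(names(overrides), names(formals(builder)))
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(builder, overrides)
  }
  merge_list <- function(defaults, overrides) {
    if (is.null(overrides)) return(defaults)
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) > 0)
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults, overrides)
  }
  base <- run_config()
  run_config(task = merge_section(task_config, raw$task),
             cohort = merge_section(cohort_spec, raw$cohort),
             fit = merge_section(fit_config, raw$fit),
             glm = merge_list(base$glm, raw$glm),
             stats = merge_list(base$stats, raw$stats),
             sims = merge_list(base$sims, raw$sims),
             out_dir = if (is.null(raw$out_dir)) NULL else raw$out_dir,
             seed = if (is.null(raw$seed)) 1L else raw$seed)
}

# residualized post-treatment severity: residuals of post ~ pre
.residualized_bdi <- function(pre, post) {
  keep <- !is.na(post)
  res <- rep(NA_real_, length(post))
  res[keep] <- stats::residuals(lm(post[keep] ~ pre[keep]))
  res
}

#' Run the end-to-end synthetic analysis
#'
#' Executes the full pipeline on one synthetic cohort: simulate -> fit ->
#' validate (predictive, generative, optional recovery) -> trial-wise
#' integrated-evidence regressors -> first-level design, synthetic BOLD and
#' OLS estimation -> group ANCOVAs on behaviour (parameter estimates,
#' accuracy) and on the estimated EA betas -> brain-behaviour bend
#' correlations with BH adjustment -> cross-validated classification of
#' treatment response with a permutation null. Each subject's true EA beta
#' scales the EA column of their synthetic BOLD series; behavioural
#' parameters are drawn from group-identical distributions unless the
#' cohort spec says otherwise, mirroring a behavioural null with a neural
#' group difference.
#'
#' If `config$out_dir` is set, intermediate tables, a summary JSON and a
#' manifest (config hash, seeds, output hashes) are written there.
#'
#' @param config a [run_config] object.
#' @return a report list with elements `cohort_rates`, `fits` (per-subject
#'   parameter table), `predictive`, `generative`, `recovery` (NULL if
#'   skipped), `ea_betas`, `behavioural_ancova`, `ea_ancova`,
#'   `correlations`, `classification`, and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed
  dt <- config$sims$dt

  cohort <- stage("simulate", generate_cohort(config$cohort, config$task,
                                              seed = seed, dt = dt))
  subjects <- cohort$subjects
  gt <- cohort$ground_truth
  n <- length(subjects)

  fits <- stage("fit", lapply(seq_len(n), function(i)
    fit_subject(subjects[[i]], config$fit, seed = seed + 7L * i)))

  predictive <- stage("validate-predictive", {
    per <- lapply(seq_len(n), function(i)
      predictive_check(subjects[[i]], fits[[i]]))
    tab <- do.call(rbind, lapply(per, as.data.frame))
    list(table = tab,
         accuracy = percentage_bend_correlation(tab$obs_accuracy,
                                                tab$pred_accuracy),
         rt = percentage_bend_correlation(tab$obs_rt, tab$pred_rt))
  })

  generative <- stage("validate-generative",
    generative_check(subjects, fits, config$task,
                     n_sims = config$sims$n_sims_generative, dt = dt,
                     seed = seed + 211L))

  recovery <- if (config$sims$n_recovery >= 10)
    stage("validate-recovery",
          parameter_recovery(config$sims$n_recovery, config$cohort,
                             config$task, config$fit, seed = seed + 307L,
                             dt = dt)) else NULL

  first_level <- stage("first-level", {
    hrf <- double_gamma_hrf(config$glm$hrf_resolution)
    out <- lapply(seq_len(n), function(i) {
      f <- fits[[i]]
      areas <- trial_areas(f$trajectory$drift, f$params$a, f$params$ndt,
                           n_sims = config$sims$n_sims_area, dt = dt,
                           seed = seed + 401L + i)
      # a subject without late trials legitimately loses the out_late
      # column; inside the pipeline that is expected, not a warning
      des <- withCallingHandlers(
        build_design(subjects[[i]], f, areas, tr = config$glm$tr,
                     hrf = hrf),
        warning = function(w) {
          if (grepl("dropped all-zero", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      betas <- c(dec_ea = subjects[[i]]$true_ea_beta,
                 config$glm$nuisance_betas)
      y <- synth_bold(des, betas, noise_sd = config$glm$noise_sd,
                      ar_coefficient = config$glm$ar,
                      seed = seed + 601L + i)
      est <- ols_fit(des, y)
      list(ea_beta_hat = unname(est$betas["dec_ea"]),
           ea_beta_se = unname(est$se["dec_ea"]))
    })
    data.frame(subject_id = gt$subject_id,
               true_ea_beta = gt$true_ea_beta,
               ea_beta_hat = vapply(out, `[[`, numeric(1), "ea_beta_hat"),
               ea_beta_se = vapply(out, `[[`, numeric(1), "ea_beta_se"))
  })

  fit_tab <- data.frame(
    subject_id = gt$subject_id, group = gt$group, pre_bdi = gt$pre_bdi,
    post_bdi = gt$post_bdi,
    kappa = vapply(fits, function(f) f$params$kappa, numeric(1)),
    a = vapply(fits, function(f) f$params$a, numeric(1)),
    alpha = vapply(fits, function(f) f$params$alpha, numeric(1)),
    ndt = vapply(fits, function(f) f$params$ndt, numeric(1)),
    accuracy = vapply(seq_len(n), function(i) {
      tr <- subjects[[i]]$trials
      mean(tr$accuracy[!tr$late])
    }, numeric(1)),
    converged = vapply(fits, `[[`, logical(1), "converged"))

  group_stats <- stage("group-stats", {
    beh <- lapply(c("kappa", "a", "alpha", "ndt", "accuracy"), function(v)
      ancova_group_effect(fit_tab[[v]], fit_tab$group, fit_tab$pre_bdi))
    names(beh) <- c("kappa", "a", "alpha", "ndt", "accuracy")
    ea <- ancova_group_effect(first_level$ea_beta_hat, fit_tab$group,
                              fit_tab$pre_bdi)
    res_bdi <- .residualized_bdi(fit_tab$pre_bdi, fit_tab$post_bdi)
    keep <- !is.na(res_bdi)
    brain_beh <- percentage_bend_correlation(
      first_level$ea_beta_hat[keep], res_bdi[keep],
      beta_bend = config$stats$bend_beta)
    raw_p <- c(vapply(beh, `[[`, numeric(1), "p"), ea = ea$p,
               brain_behaviour = brain_beh$p)
    list(behavioural = beh, ea = ea, brain_behaviour = brain_beh,
         p_adjusted = bh_adjust(raw_p))
  })

  classification <- stage("classify", {
    feats <- cbind(ea_beta = first_level$ea_beta_hat)
    cv <- cv_classify_auc(feats, fit_tab$group, k = config$stats$k_folds,
                          seed = seed + 907L)
    perm <- permutation_pvalue(feats, fit_tab$group, cv$auc,
                               n_perm = config$stats$n_perm,
                               k = config$stats$k_folds, seed = seed + 911L)
    list(auc = cv$auc, p_perm = perm$p_perm, n_perm = perm$n_perm)
  })

  report <- list(
    cohort_rates = cohort_rates(gt$group, gt$completed),
    fits = fit_tab,
    predictive = predictive,
    generative = generative,
    recovery = recovery,
    ea_betas = first_level,
    behavioural_ancova = group_stats$behavioural,
    ea_ancova = group_stats$ea,
    correlations = list(brain_behaviour = group_stats$brain_behaviour,
                        p_adjusted = group_stats$p_adjusted),
    classification = classification,
    config = config)

  if (!is.null(config$out_dir))
    stage("write-outputs", .write_pipeline_outputs(report, cohort, config))
  report
}

# Persist tables, a machine-readable summary and a manifest with hashes.
.write_pipeline_outputs <- function(report, cohort, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_behaviour(cohort$subjects, p("behaviour.csv"))
  write_clinical(cohort$ground_truth, p("clinical.csv"))
  write.csv(cohort$ground_truth, p("ground_truth.csv"), row.names = FALSE)
  write.csv(report$fits, p("fit_results.csv"), row.names = FALSE)
  write.csv(report$ea_betas, p("ea_betas.csv"), row.names = FALSE)
  write.csv(report$generative$table, p("generative_check.csv"),
            row.names = FALSE)
  if (!is.null(report$recovery))
    write.csv(report$recovery$table, p("recovery.csv"), row.names = FALSE)
  summary <- list(
    cohort_rates = report$cohort_rates,
    behavioural_p = lapply(report$behavioural_ancova, `[[`, "p"),
    ea_group_effect = report$ea_ancova[c("coefficient", "t", "p")],
    brain_behaviour_r = report$correlations$brain_behaviour$r,
    p_adjusted = as.list(report$correlations$p_adjusted),
    auc = report$classification$auc,
    p_perm = report$classification$p_perm,
    generative_r = lapply(report$generative$correlations, `[[`, "r"),
    predictive_r = list(accuracy = report$predictive$accuracy$r,
                        rt = report$predictive$rt$r),
    seed = config$seed)
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- list.files(config$out_dir, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("rlddm")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(.write_config_tmp(config))),
    outputs = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(config$out_dir)
}

# serialize the config deterministically for hashing
.write_config_tmp <- function(config) {
  tmp <- file.path(tempdir(), "rlddm-config-hash.json")
  cfg <- config
  cfg$out_dir <- NULL
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  tmp
}
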