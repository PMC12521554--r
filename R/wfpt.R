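#' Wiener first-passage-time density (Navarro-Fuss approximation)
#'
#' Density of absorption times at the LOWER boundary of a drift-diffusion
#' process with unit diffusion coefficient, drift `drift`, boundary
#' separation `a` and relative start `w` (0.5 = unbiased). Both the
#' small-time and the large-time series expansions are implemented; with
#' `method = "auto"` the series needing fewer terms for truncation error
#' `<= eps` is used per evaluation point. The upper-boundary density is
#' obtained by the reflection `(drift, w) -> (-drift, 1 - w)`. Nonpositive
#' `t` returns density 0 (by contract, keeping likelihoods robust at the
#' non-decision-time edge).
#'
#' @param t decision time(s) in seconds (vectorized).
#' @param drift drift rate.
#' @param a boundary separation, > 0.
#' @param w relative starting point in (0, 1).
#' @param eps series truncation error bound.
#' @param method "auto" (fewest terms), or force the "small"- or
#'   "large"-time expansion (used for series cross-checks).
#' @return numeric vector of densities.
#' @export
wfpt_density <- function(t, drift, a, w = 0.5, eps = 1e-7,
                         method = c("auto", "small", "large")) {
  method <- match.arg(method)
  if (a <= 0) stop("boundary separation a must be positive")
  if (w <= 0 || w >= 1) stop("relative start w must lie in (0, 1)")
  if (any(is.na(c(drift, a, w, eps)))) stop("NaN parameter input")
  if (eps <= 0) stop("eps must be positive")
  vapply(t, function(ti) {
    if (is.na(ti)) return(NA_real_)
    if (ti <= 0) return(0)
    tt <- ti / a^2
    ks <- if (2 * sqrt(2 * pi * tt) * eps < 1)
      max(2 + sqrt(-2 * tt * log(2 * eps * sqrt(2 * pi * tt))),
          sqrt(tt) + 1) else 2
    kl <- if (pi * tt * eps < 1)
      max(sqrt(-2 * log(pi * tt * eps) / (pi^2 * tt)), 1 / (pi * sqrt(tt)))
    else 1 / (pi * sqrt(tt))
    use_small <- switch(method, auto = ks < kl, small = TRUE, large = FALSE)
    p <- if (use_small) {
      K <- ceiling(ks)
      ks_seq <- seq(-floor((K - 1) / 2), ceiling((K - 1) / 2))
      z <- w + 2 * ks_seq
      sum(z * exp(-z^2 / (2 * tt))) / sqrt(2 * pi * tt^3)
    } else {
      K <- ceiling(kl)
      kk <- seq_len(K)
      pi * sum(kk * exp(-kk^2 * pi^2 * tt / 2) * sin(kk * pi * w))
    }
    max(p * exp(-drift * a * w - drift^2 * ti / 2) / a^2, 0)
  }, numeric(1))
}

#' Fitting configuration for MAP estimation
#'
#' Priors are independent Gaussians in the unconstrained parameter space
#' with variance 10 each. The means put `kappa` and `a` at native value 1
#' (0 in log space), `alpha` at 0 in logit space, and the non-decision time
#' at 0.1 s through its scaled logit (capped when a subject's minimum RT is
#' close to 0.1 s).
#'
#' @param prior_variances length-4 prior variances in unconstrained space.
#' @param eps WFPT series truncation error per density evaluation.
#' @param n_restarts number of optimizer starts (prior mean plus random
#'   perturbations).
#' @param maxit iteration cap per optimizer run.
#' @param min_trials minimum number of usable (non-late) trials.
#' @param ndt_prior_native prior mean for the non-decision time, seconds.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(prior_variances = rep(10, 4), eps = 1e-7,
                       n_restarts = 10, maxit = 300, min_trials = 30,
                       ndt_prior_native = 0.1) {
  if (eps <= 0) stop("eps must be positive")
  if (any(prior_variances <= 0)) stop("prior variances must be positive")
  if (n_restarts < 1) stop("n_restarts must be at least 1")
  structure(list(prior_variances = prior_variances, eps = eps,
                 n_restarts = as.integer(n_restarts), maxit = maxit,
                 min_trials = min_trials,
                 ndt_prior_native = ndt_prior_native),
            class = "fit_config")
}

# unconstrained-space prior means given the subject's ndt upper bound
.prior_means <- function(config, ndt_upper) {
  c(0, 0, 0, qlogis(min(config$ndt_prior_native / ndt_upper, 0.95)))
}

# unit-scaled feedback from stored signed points
.feedback_unit <- function(feedback) sign(feedback)

#' Per-trial RLDDM log-likelihood
#'
#' The trial's drift rate is coded relative to the chosen stimulus,
#' `v_t = kappa * (Q_chosen - Q_unchosen)`, and the observed response is
#' scored at the boundary the drift favours when the model predicts the
#' choice: the returned value is the log WFPT density at decision time
#' `rt - ndt` with drift `-v_t` at the lower boundary (equivalently, `+v_t`
#' at the upper). Model-predicted choices (positive `v_t`) are therefore
#' the fast, likely absorptions.
#'
#' @param rt observed response time (s) of a non-late trial.
#' @param q_chosen,q_unchosen current Q values.
#' @param params an [rlddm_params] object.
#' @param eps WFPT truncation error.
#' @return log-likelihood (log density; `-Inf` clamps to `log(1e-300)` when
#'   `rt <= ndt`).
#' @export
trial_loglik <- function(rt, q_chosen, q_unchosen, params, eps = 1e-7) {
  v <- params$kappa * (q_chosen - q_unchosen)
  f <- mapply(function(ti, vi)
    wfpt_density(ti, vi, params$a, w = 0.5, eps = eps),
    rt - params$ndt, -v)
  log(pmax(f, 1e-300))
}

#' Q-value, drift-rate and prediction-error trajectories
#'
#' Replays the learning recursion over a subject's trials at fixed
#' parameters: Q values of both stimuli at trial onset, the trial drift rate
#' (chosen-minus-unchosen coding; NA on late trials), the absolute Q
#' difference and the signed reward prediction error. Late trials update
#' nothing.
#'
#' @param trials a `subject_dataset` trials data.frame.
#' @param params an [rlddm_params] object.
#' @return data.frame with columns `trial, q0, q1, drift, abs_dq, rpe`.
#' @export
drift_trajectory <- function(trials, params) {
  n <- nrow(trials)
  q <- c(0, 0)
  out <- data.frame(trial = trials$trial, q0 = NA_real_, q1 = NA_real_,
                    drift = NA_real_, abs_dq = NA_real_, rpe = NA_real_)
  fb <- .feedback_unit(trials$feedback)
  for (i in seq_len(n)) {
    out$q0[i] <- q[1]
    out$q1[i] <- q[2]
    out$abs_dq[i] <- abs(q[1] - q[2])
    if (!trials$late[i]) {
      c_i <- trials$chosen_stim[i] + 1L
      out$drift[i] <- params$kappa * (q[c_i] - q[3L - c_i])
      out$rpe[i] <- fb[i] - q[c_i]
      q[c_i] <- rw_update(q[c_i], fb[i], params$alpha)
    }
  }
  out
}

#' Negative log-posterior of the hybrid RLDDM
#'
#' Maps the unconstrained vector `theta = (log kappa, log a, logit alpha,
#' logit(ndt/ndt_upper))` to native space, replays the Q/drift recursion
#' over the subject's trials (late trials skipped for likelihood and
#' learning), sums the per-trial WFPT log-likelihoods, and adds independent
#' Gaussian log-priors in the unconstrained space. Returns the negative.
#'
#' @param theta unconstrained parameter vector (length 4).
#' @param dataset a `subject_dataset`.
#' @param config a [fit_config] object.
#' @param ndt_upper upper bound for the non-decision time; defaults to just
#'   below the subject's minimum RT.
#' @param use_prior set FALSE for the pure negative log-likelihood.
#' @param engine "cpp" (fast path used by the fitter) or "r" (reference
#'   implementation via [wfpt_density()] and [trial_loglik()]).
#' @return scalar negative log-posterior.
#' @export
neg_log_posterior <- function(theta, dataset, config = fit_config(),
                              ndt_upper = NULL, use_prior = TRUE,
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (!all(is.finite(theta))) stop("non-finite theta")
  trials <- dataset$trials
  if (is.null(ndt_upper)) ndt_upper <- 0.999 * min(trials$rt, na.rm = TRUE)
  params <- params_from_unconstrained(theta, ndt_upper)
  if (engine == "cpp") {
    chosen <- trials$chosen_stim
    chosen[is.na(chosen)] <- 0L
    fb <- .feedback_unit(trials$feedback)
    fb[is.na(fb)] <- 0
    nll <- rlddm_negloglik_cpp(ifelse(is.na(trials$rt), 0, trials$rt),
                               as.integer(chosen), fb,
                               as.logical(trials$late), params$kappa,
                               params$a, params$alpha, params$ndt,
                               config$eps)
  } else {
    traj <- drift_trajectory(trials, params)
    ok <- !trials$late
    c_i <- trials$chosen_stim[ok] + 1L
    qc <- ifelse(c_i == 1L, traj$q0[ok], traj$q1[ok])
    qu <- ifelse(c_i == 1L, traj$q1[ok], traj$q0[ok])
    nll <- -sum(trial_loglik(trials$rt[ok], qc, qu, params,
                             eps = config$eps))
  }
  if (use_prior) {
    mu <- .prior_means(config, ndt_upper)
    nll <- nll - sum(stats::dnorm(theta, mu, sqrt(config$prior_variances),
                                  log = TRUE))
  }
  nll
}

#' Fit the hybrid RLDDM to one subject by MAP
#'
#' Multi-start quasi-Newton optimization (BFGS with numerical gradients) of
#' [neg_log_posterior()] over the unconstrained parameters: one start at the
#' prior mean plus `n_restarts - 1` random perturbations (prior mean
#' +/- 1 SD draws). The best optimum is returned together with the spread of
#' converged objective values across restarts and the Q/drift trajectories
#' at the optimum.
#'
#' @param dataset a `subject_dataset` with at least `min_trials` non-late
#'   trials.
#' @param config a [fit_config] object.
#' @param seed integer seed for the restart draws.
#' @return an object of class `fit_result`: `params` ([rlddm_params]),
#'   `theta`, `neg_log_posterior`, `converged`, `restart_spread`,
#'   `ndt_upper`, `n_usable`, and `trajectory` (per-trial Q/drift/RPE).
#' @export
fit_subject <- function(dataset, config = fit_config(), seed = 1) {
  trials <- dataset$trials
  n_usable <- sum(!trials$late)
  if (n_usable < config$min_trials)
    stop("fewer than ", config$min_trials, " usable trials")
  ndt_upper <- 0.999 * min(trials$rt, na.rm = TRUE)
  mu <- .prior_means(config, ndt_upper)
  set.seed(seed)
  starts <- rbind(mu, matrix(rnorm(4 * (config$n_restarts - 1), mu, 1),
                             ncol = 4, byrow = TRUE))
  # large finite penalty outside the representable region (exp/plogis
  # saturation) keeps line searches from killing a restart
  obj <- function(th) {
    val <- tryCatch(neg_log_posterior(th, dataset, config, ndt_upper),
                    error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }
  fits <- apply(starts, 1, function(s) {
    res <- tryCatch(optim(s, obj, method = "BFGS",
                          control = list(maxit = config$maxit)),
                    error = function(e) NULL)
    res
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all restarts failed")
  values <- vapply(fits, `[[`, numeric(1), "value")
  best <- fits[[which.min(values)]]
  params <- params_from_unconstrained(best$par, ndt_upper)
  structure(list(params = params, theta = best$par,
                 neg_log_posterior = best$value,
                 converged = best$convergence == 0,
                 restart_spread = max(values) - min(values),
                 ndt_upper = ndt_upper, n_usable = n_usable,
                 trajectory = drift_trajectory(trials, params)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "RLDDM MAP fit: kappa=%.3f a=%.3f alpha=%.3f ndt=%.3f | -logpost=%.2f%s\n",
    x$params$kappa, x$params$a, x$params$alpha, x$params$ndt,
    x$neg_log_posterior, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Parameter-recovery study
#'
#' Draws true parameters from the cohort generating distribution, simulates
#' each synthetic subject on the task, refits by MAP, and reports the 10%
#' percentage-bend correlation between true and recovered values per
#' parameter. Failed fits are listed, not fatal.
#'
#' @param n_subjects number of synthetic subjects (>= 10).
#' @param spec a [cohort_spec] supplying the generating distribution.
#' @param config a [task_config] object.
#' @param fit_cfg a [fit_config] object.
#' @param seed master seed.
#' @param dt Euler step for simulation.
#' @return list with `table` (true and recovered values per subject) and
#'   `correlations` (per-parameter bend correlation results), plus
#'   `failures`.
#' @export
parameter_recovery <- function(n_subjects = 30, spec = cohort_spec(),
                               config = task_config(),
                               fit_cfg = fit_config(), seed = 1, dt = 1e-3) {
  if (n_subjects < 10) stop("n_subjects must be at least 10")
  set.seed(seed)
  theta_true <- matrix(rnorm(4 * n_subjects, rep(spec$param_means,
                                                 each = n_subjects),
                             rep(spec$param_sds, each = n_subjects)),
                       ncol = 4)
  rows <- vector("list", n_subjects)
  failures <- character(0)
  for (i in seq_len(n_subjects)) {
    pt <- params_from_unconstrained(theta_true[i, ], spec$ndt_upper)
    ds <- simulate_agent(pt, config, seed = seed + 101L * i, dt = dt,
                         subject_id = sprintf("s%02d", i))
    fit <- tryCatch(fit_subject(ds, fit_cfg, seed = seed + i),
                    error = function(e) NULL)
    if (is.null(fit)) {
      failures <- c(failures, ds$subject_id)
      next
    }
    pr <- fit$params
    rows[[i]] <- data.frame(
      subject_id = ds$subject_id,
      parameter = c("kappa", "a", "alpha", "ndt"),
      true = c(pt$kappa, pt$a, pt$alpha, pt$ndt),
      recovered = c(pr$kappa, pr$a, pr$alpha, pr$ndt))
  }
  table <- do.call(rbind, rows)
  correlations <- lapply(split(table, table$parameter), function(d) {
    percentage_bend_correlation(d$true, d$recovered)
  })
  list(table = table, correlations = correlations, failures = failures)
}

#' Predictive check of a fitted subject
#'
#' Model predictions at the fitted parameters: predicted choice accuracy per
#' trial from the sign of the fitted dynamic drift rate (the model predicts
#' the stimulus with the higher Q; ties count 0.5), and predicted mean RT
#' from the analytic mean first-passage time at `|v_t|`. Returns observed
#' and predicted subject-level means for across-subject correlation.
#'
#' @param dataset a `subject_dataset`.
#' @param fit the subject's `fit_result`.
#' @return list with `obs_accuracy`, `pred_accuracy`, `obs_rt`, `pred_rt`.
#' @export
predictive_check <- function(dataset, fit) {
  trials <- dataset$trials
  ok <- !trials$late
  traj <- fit$trajectory
  q_high <- ifelse(trials$high_prob_stim == 0, traj$q0, traj$q1)
  q_low <- ifelse(trials$high_prob_stim == 0, traj$q1, traj$q0)
  pred_correct <- ifelse(q_high > q_low, 1, ifelse(q_high < q_low, 0, 0.5))
  v_abs <- fit$params$kappa * abs(q_high - q_low)
  pred_rt <- mean_rt_analytic(v_abs, fit$params$a, fit$params$ndt)
  list(obs_accuracy = mean(trials$accuracy[ok]),
       pred_accuracy = mean(pred_correct[ok]),
       obs_rt = mean(trials$rt[ok]),
       pred_rt = mean(pred_rt[ok]))
}

#' Generative check: observed vs model-simulated behaviour
#'
#' For each subject, re-simulates the full task `n_sims` times at the fitted
#' parameters and compares, per choice category (choices of the currently
#' high- vs low-probability stimulus), the observed and simulated mean RT
#' and choice proportion. The four across-subject 10% bend correlations
#' (RT and choice proportion, high and low category) summarize generative
#' adequacy.
#'
#' @param subjects list of `subject_dataset` objects.
#' @param fits list of matching `fit_result` objects.
#' @param config the [task_config] the data were collected under.
#' @param n_sims simulations per subject (reference analyses use 5000).
#' @param dt Euler step.
#' @param seed integer seed.
#' @return list with `table` (per-subject observed/simulated cell means) and
#'   `correlations` (named list of bend-correlation results for
#'   `rt_high, rt_low, choice_high, choice_low`).
#' @export
generative_check <- function(subjects, fits, config = task_config(),
                             n_sims = 5000, dt = 1e-3, seed = 1) {
  stopifnot(length(subjects) == length(fits))
  if (length(subjects) < 5) stop("need at least 5 fitted subjects")
  set.seed(seed)
  rows <- lapply(seq_along(subjects), function(i) {
    tr <- subjects[[i]]$trials
    ok <- !tr$late
    hi <- ok & tr$accuracy == 1
    lo <- ok & tr$accuracy == 0
    p <- fits[[i]]$params
    sim <- generative_sim_cpp(as.integer(n_sims), config$n_trials,
                              config$p_high, config$p_low,
                              config$reversal_criterion_k,
                              config$buffer_trials[1],
                              config$buffer_trials[2],
                              config$response_deadline, p$kappa, p$a,
                              p$alpha, p$ndt, dt)
    data.frame(
      subject_id = subjects[[i]]$subject_id,
      obs_rt_high = mean(tr$rt[hi]), obs_rt_low = mean(tr$rt[lo]),
      obs_choice_high = sum(hi) / sum(ok),
      obs_choice_low = sum(lo) / sum(ok),
      sim_rt_high = sim[["rt_sum_high"]] / sim[["n_high"]],
      sim_rt_low = sim[["rt_sum_low"]] / sim[["n_low"]],
      sim_choice_high = sim[["n_high"]] / (sim[["n_high"]] + sim[["n_low"]]),
      sim_choice_low = sim[["n_low"]] / (sim[["n_high"]] + sim[["n_low"]]))
  })
  table <- do.call(rbind, rows)
  cell_cor <- function(obs, sim) {
    keep <- complete.cases(obs, sim)
    percentage_bend_correlation(obs[keep], sim[keep])
  }
  correlations <- list(
    rt_high = cell_cor(table$obs_rt_high, table$sim_rt_high),
    rt_low = cell_cor(table$obs_rt_low, table$sim_rt_low),
    choice_high = cell_cor(table$obs_choice_high, table$sim_choice_high),
    choice_low = cell_cor(table$obs_choice_low, table$sim_choice_low))
  list(table = table, correlations = correlations)
}
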