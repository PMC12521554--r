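#' RLDDM parameter set
#'
#' The hybrid model has four free parameters: the drift scaling `kappa`
#' (evidence per second per unit Q-value difference), the boundary separation
#' `a` (evidence units; response caution), the learning rate `alpha` of the
#' Rescorla-Wagner update, and the non-decision time `ndt` (seconds of
#' encoding/motor latency added to the decision time).
#'
#' @param kappa drift-rate scaling, > 0.
#' @param a boundary separation, > 0. The accumulator starts unbiased at
#'   `a/2` and is absorbed at 0 or `a`.
#' @param alpha learning rate in (0, 1).
#' @param ndt non-decision time in seconds, > 0.
#' @return an object of class `rlddm_params` (a named list).
#' @examples
#' rlddm_params(kappa = 3, a = 1.3, alpha = 0.3, ndt = 0.3)
#' @export
rlddm_params <- function(kappa, a, alpha, ndt) {
  vals <- c(kappa = kappa, a = a, alpha = alpha, ndt = ndt)
  if (!all(is.finite(vals))) stop("RLDDM parameters must be finite")
  if (kappa <= 0) stop("kappa must be positive")
  if (a <= 0) stop("boundary separation a must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (ndt <= 0) stop("ndt must be positive")
  structure(list(kappa = kappa, a = a, alpha = alpha, ndt = ndt),
            class = "rlddm_params")
}

#' @export
print.rlddm_params <- function(x, ...) {
  cat(sprintf("RLDDM parameters: kappa=%.3f a=%.3f alpha=%.3f ndt=%.3f s\n",
              x$kappa, x$a, x$alpha, x$ndt))
  invisible(x)
}

#' Map RLDDM parameters between native and unconstrained space
#'
#' Fitting and cohort generation operate on an unconstrained vector
#' `theta = (log kappa, log a, logit alpha, logit(ndt / ndt_upper))`, which
#' preserves each parameter's natural bounds. `ndt_upper` is the upper bound
#' on the non-decision time (for fitting, the subject's minimum RT).
#'
#' @param params an [rlddm_params] object.
#' @param theta numeric vector of length 4 in unconstrained space.
#' @param ndt_upper upper bound for the non-decision time (seconds).
#' @return `params_to_unconstrained` returns a numeric 4-vector;
#'   `params_from_unconstrained` returns an [rlddm_params] object.
#' @export
params_to_unconstrained <- function(params, ndt_upper) {
  stopifnot(inherits(params, "rlddm_params"), ndt_upper > params$ndt)
  c(log(params$kappa), log(params$a), qlogis(params$alpha),
    qlogis(params$ndt / ndt_upper))
}

#' @rdname params_to_unconstrained
#' @export
params_from_unconstrained <- function(theta, ndt_upper) {
  stopifnot(length(theta) == 4, all(is.finite(theta)), ndt_upper > 0)
  rlddm_params(kappa = exp(theta[1]), a = exp(theta[2]),
               alpha = plogis(theta[3]), ndt = ndt_upper * plogis(theta[4]))
}

#' Rescorla-Wagner value update
#'
#' `Q <- Q + alpha * (R - Q)` for the chosen stimulus only; the unchosen
#' stimulus keeps its value (the caller is responsible for updating only the
#' chosen one). Feedback is unit-scaled (+1 reward, -1 punishment), keeping Q
#' in `[-1, 1]` from a zero start.
#'
#' @param q current expected value.
#' @param r unit-scaled feedback.
#' @param alpha learning rate in `[0, 1]`.
#' @return the updated value.
#' @examples
#' rw_update(0, 1, 0.5) # 0.5
#' @export
rw_update <- function(q, r, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  q + alpha * (r - q)
}

#' Dynamic drift rate
#'
#' The trial's drift rate is the signed Q-value difference scaled by `kappa`:
#' `v_t = kappa * (q1 - q2)`. It is antisymmetric in its value arguments.
#'
#' @param q1,q2 expected values of the two stimuli.
#' @param kappa drift scaling.
#' @return the drift rate (evidence per second).
#' @export
dynamic_drift <- function(q1, q2, kappa) {
  if (!all(is.finite(c(q1, q2, kappa)))) stop("non-finite input")
  kappa * (q1 - q2)
}

#' Simulate a single bounded evidence-accumulation path
#'
#' Euler-Maruyama simulation of a drift-diffusion path with unit diffusion
#' coefficient: increments `drift * dt + N(0, dt)`, start at `a/2`, absorbed
#' at the first step at or beyond 0 or `a` (the absorbing step is clipped to
#' the bound). The area under the path (evidence measured from 0, rectangle
#' rule over post-step values) is the trial's integrated decision evidence.
#'
#' @param drift drift rate.
#' @param a boundary separation, > 0.
#' @param ndt non-decision time added to the decision time to give `rt`.
#' @param dt integration step in seconds.
#' @param max_time censoring horizon in seconds; a path still unabsorbed at
#'   `max_time` is returned with `boundary = "none"`.
#' @param seed optional integer seed.
#' @return an object of class `ea_trace`: list with `values` (the path,
#'   starting at `a/2`), `dt`, `decision_time`, `boundary` ("upper", "lower"
#'   or "none"), `area`, and `rt = decision_time + ndt`.
#' @export
simulate_ddm_path <- function(drift, a, ndt = 0, dt = 1e-3, max_time = 10,
                              seed = NULL) {
  if (a <= 0) stop("boundary separation a must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (dt >= max_time) stop("dt must be smaller than max_time")
  if (max_time <= ndt) stop("max_time must exceed ndt")
  if (!is.null(seed)) set.seed(seed)
  n_max <- ceiling(max_time / dt)
  incr <- drift * dt + rnorm(n_max, 0, sqrt(dt))
  path <- a / 2 + cumsum(incr)
  hit <- which(path >= a | path <= 0)
  if (length(hit) == 0L) {
    boundary <- "none"
    n_steps <- n_max
  } else {
    n_steps <- hit[1L]
    boundary <- if (path[n_steps] >= a) "upper" else "lower"
    path <- path[seq_len(n_steps)]
    path[n_steps] <- if (boundary == "upper") a else 0
  }
  area <- sum(pmin(pmax(path, 0), a)) * dt
  structure(list(values = c(a / 2, path), dt = dt,
                 decision_time = n_steps * dt, boundary = boundary,
                 area = area, rt = n_steps * dt + ndt),
            class = "ea_trace")
}

#' Analytic mean response time of the diffusion process
#'
#' For an unbiased start and unit diffusion, the expected decision time is
#' `(a / (2 v)) * tanh(a v / 2)`, plus the non-decision time. At `v = 0` the
#' limit `a^2 / 4` is used. The expression is even in `v`.
#'
#' @param drift drift rate (may be 0).
#' @param a boundary separation, > 0.
#' @param ndt non-decision time in seconds.
#' @return expected RT in seconds.
#' @examples
#' mean_rt_analytic(1, 2, 0.3) # tanh(1) + 0.3
#' @export
mean_rt_analytic <- function(drift, a, ndt = 0) {
  if (any(a <= 0)) stop("boundary separation a must be positive")
  dt_mean <- ifelse(abs(drift) < 1e-10, a^2 / 4,
                    (a / (2 * drift)) * tanh(a * drift / 2))
  dt_mean + ndt
}

#' Analytic absorption probability at the drift-favoured boundary
#'
#' For an unbiased start and unit diffusion the probability of absorption at
#' the boundary the drift points toward is `1 / (1 + exp(-|v| * a))`; 0.5 at
#' `v = 0`. Used as the closed-form oracle for the path simulator.
#'
#' @inheritParams mean_rt_analytic
#' @return probability in `[0.5, 1)`.
#' @export
choice_prob_analytic <- function(drift, a) {
  if (any(a <= 0)) stop("boundary separation a must be positive")
  1 / (1 + exp(-abs(drift) * a))
}

#' Integrated decision evidence for a given drift
#'
#' Monte-Carlo mean of the area under the accumulation path (from stimulus
#' onset to absorption) over `n_sims` simulated paths at a fixed drift.
#' Censored paths (unabsorbed at `max_time`) contribute their truncated area
#' and are counted in `n_censored`.
#'
#' @inheritParams simulate_ddm_path
#' @param n_sims number of simulated paths (the reference regressor uses
#'   5000 per trial).
#' @return list with `mean_area`, `se`, `n_censored`, `n_sims`.
#' @export
integrated_evidence <- function(drift, a, ndt = 0, n_sims = 5000, dt = 1e-3,
                                max_time = 10, seed = NULL) {
  if (n_sims < 1) stop("n_sims must be at least 1")
  if (a <= 0) stop("boundary separation a must be positive")
  if (!is.null(seed)) set.seed(seed)
  sims <- ddm_paths_cpp(as.integer(n_sims), drift, a, dt, max_time)
  if (all(sims$boundary == 0L)) stop("all paths censored; increase max_time")
  areas <- sims$area
  list(mean_area = mean(areas),
       se = sd(areas) / sqrt(length(areas)),
       n_censored = sum(sims$boundary == 0L),
       n_sims = n_sims)
}

#' Per-trial integrated-evidence estimates for a fitted subject
#'
#' Computes, for every non-late trial, the Monte-Carlo mean area under the
#' accumulation curve at that trial's fitted drift rate. This is the
#' trial-wise parametric modulator of the first-level fMRI design.
#'
#' @param drifts numeric vector of per-trial drift rates (NA for late trials).
#' @param a,ndt fitted boundary separation and non-decision time.
#' @param n_sims simulations per trial.
#' @param dt,max_time integration step and censoring horizon.
#' @param seed optional integer seed.
#' @return data.frame with `trial`, `mean_area`, `se`, `n_censored`.
#' @export
trial_areas <- function(drifts, a, ndt, n_sims = 5000, dt = 1e-3,
                        max_time = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(trial = seq_along(drifts) - 1L, mean_area = NA_real_,
                    se = NA_real_, n_censored = NA_integer_)
  for (i in seq_along(drifts)) {
    if (is.na(drifts[i])) next
    ie <- integrated_evidence(drifts[i], a, ndt, n_sims = n_sims, dt = dt,
                              max_time = max_time)
    out$mean_area[i] <- ie$mean_area
    out$se[i] <- ie$se
    out$n_censored[i] <- ie$n_censored
  }
  out
}
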