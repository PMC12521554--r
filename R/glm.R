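#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak at 6 s, undershoot peak
#' at 16 s, undershoot ratio 1/6, unit rate), sampled on a regular grid and
#' normalized to peak 1. These are the common canonical values used by
#' first-level fMRI packages.
#'
#' @param resolution_s sampling step of the kernel in seconds (<= 0.1).
#' @param length_s kernel support in seconds.
#' @param peak,undershoot gamma shape parameters of response and undershoot.
#' @param ratio undershoot amplitude relative to the response.
#' @return list with `t` (time grid) and `values` (kernel), class `hrf`.
#' @export
double_gamma_hrf <- function(resolution_s = 0.05, length_s = 32,
                             peak = 6, undershoot = 16, ratio = 1 / 6) {
  if (resolution_s <= 0) stop("resolution must be positive")
  if (resolution_s > 0.1) stop("resolution must be at most 0.1 s")
  t <- seq(0, length_s, by = resolution_s)
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h <- h / max(h)
  structure(list(t = t, values = h), class = "hrf")
}

#' Event regressor (stick or boxcar with optional parametric modulation)
#'
#' @param name column label.
#' @param onsets event onsets in seconds (nondecreasing).
#' @param durations event durations in seconds (0 = stick function).
#' @param modulation optional per-event weights (parametric modulator).
#' @return an object of class `event_regressor`.
#' @export
event_regressor <- function(name, onsets, durations = 0, modulation = NULL) {
  if (is.unsorted(onsets)) stop("onsets must be nondecreasing")
  if (length(durations) == 1) durations <- rep(durations, length(onsets))
  if (length(durations) != length(onsets))
    stop("durations must match onsets")
  if (!is.null(modulation) && length(modulation) != length(onsets))
    stop("modulation length must equal onset count")
  structure(list(name = name, onsets = onsets, durations = durations,
                 modulation = modulation), class = "event_regressor")
}

#' Write an event regressor in FSL three-column EV format
#'
#' One row per event: onset, duration, weight (tab separated). Unmodulated
#' regressors carry weight 1.
#'
#' @param reg an [event_regressor].
#' @param path output text file.
#' @export
write_fsl_ev <- function(reg, path) {
  w <- if (is.null(reg$modulation)) rep(1, length(reg$onsets)) else
    reg$modulation
  utils::write.table(data.frame(reg$onsets, reg$durations, w), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Convolve one event regressor with the HRF on a fine grid and resample at
# the TR grid. The convolution integral is approximated as res * (x * k): a
# stick of weight w is an impulse of area w (response peaks at w times the
# unit-peak kernel), a boxcar holds height w over its duration. This keeps
# columns invariant to the kernel resolution.
.convolve_regressor <- function(reg, hrf, tr, n_volumes, weights) {
  res <- hrf$t[2] - hrf$t[1]
  t_end <- n_volumes * tr
  n_fine <- ceiling(t_end / res) + 1L
  x <- numeric(n_fine)
  for (i in seq_along(reg$onsets)) {
    j0 <- floor(reg$onsets[i] / res) + 1L
    if (reg$durations[i] <= res) {
      x[j0] <- x[j0] + weights[i] / res
    } else {
      j1 <- min(floor((reg$onsets[i] + reg$durations[i]) / res) + 1L, n_fine)
      x[j0:j1] <- x[j0:j1] + weights[i]
    }
  }
  y <- res * stats::convolve(x, rev(hrf$values),
                             type = "open")[seq_len(n_fine)]
  idx <- pmin(round(seq(0, by = tr, length.out = n_volumes) / res) + 1L,
              n_fine)
  y[idx]
}

#' Build the first-level design matrix
#'
#' Assembles the integrated-evidence first-level model for one subject: at
#' the decision phase, an EA-modulated stick (the trial-wise mean area under
#' the accumulation curve), an unmodulated visual stick, an RT-modulated
#' motor stick and a |Q1-Q2|-modulated valuation stick; at the outcome
#' phase, an unmodulated visual stick, an unmodulated late-response stick
#' and a signed-RPE-modulated stick. Parametric modulators are demeaned
#' before convolution. All regressors are stick functions convolved with the
#' double-gamma HRF and resampled on the TR grid. Columns that are all zero
#' after demeaning (degenerate modulators, or no late trials) are dropped
#' with a warning.
#'
#' @param dataset a `subject_dataset`.
#' @param fit the subject's `fit_result` (supplies Q and RPE trajectories).
#' @param areas per-trial integrated evidence from [trial_areas()], aligned
#'   to `dataset$trials`.
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes; defaults to covering the session plus
#'   a 20 s tail.
#' @param hrf the HRF kernel from [double_gamma_hrf()].
#' @param demean demean parametric modulators before convolution.
#' @return an object of class `design_matrix`: list with `X` (named matrix),
#'   `tr`, `n_volumes`, `dropped` (names of dropped columns).
#' @export
build_design <- function(dataset, fit, areas, tr = 2,
                         n_volumes = NULL, hrf = double_gamma_hrf(),
                         demean = TRUE) {
  trials <- dataset$trials
  if (nrow(areas) != nrow(trials)) stop("areas must align with trials")
  if (is.null(n_volumes))
    n_volumes <- ceiling((max(trials$onset_out) + 20) / tr)
  t_end <- n_volumes * tr
  if (max(trials$onset_out) > t_end)
    stop("events extend beyond the scan window")
  ok <- !trials$late
  traj <- fit$trajectory

  dm <- function(x) if (demean) x - mean(x) else x
  regs <- list(
    ea = event_regressor("dec_ea", trials$onset_dec[ok],
                         modulation = dm(areas$mean_area[ok])),
    dec_visual = event_regressor("dec_visual", trials$onset_dec),
    motor_rt = event_regressor("dec_rt", trials$onset_dec[ok],
                               modulation = dm(trials$rt[ok])),
    valuation = event_regressor("dec_absdq", trials$onset_dec[ok],
                                modulation = dm(traj$abs_dq[ok])),
    out_visual = event_regressor("out_visual", trials$onset_out[ok]),
    out_late = event_regressor("out_late", trials$onset_out[!ok]),
    rpe = event_regressor("out_rpe", trials$onset_out[ok],
                          modulation = dm(traj$rpe[ok])))

  cols <- list()
  dropped <- character(0)
  for (reg in regs) {
    if (length(reg$onsets) == 0) {
      dropped <- c(dropped, reg$name)
      next
    }
    w <- if (is.null(reg$modulation)) rep(1, length(reg$onsets)) else
      reg$modulation
    y <- .convolve_regressor(reg, hrf, tr, n_volumes, w)
    if (all(abs(y) < 1e-12)) {
      dropped <- c(dropped, reg$name)
      next
    }
    cols[[reg$name]] <- y
  }
  if (length(dropped) > 0)
    warning("dropped all-zero column(s): ", paste(dropped, collapse = ", "))
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  structure(list(X = X, tr = tr, n_volumes = n_volumes, dropped = dropped),
            class = "design_matrix")
}

#' Synthetic BOLD time series from a design
#'
#' `series = X beta + AR(1) noise` with Gaussian innovations of standard
#' deviation `noise_sd` and autoregressive coefficient `ar_coefficient`.
#' Deterministic given the seed.
#'
#' @param design a `design_matrix`.
#' @param true_betas numeric vector matching the design columns (named
#'   vectors are matched by column name).
#' @param noise_sd innovation standard deviation.
#' @param ar_coefficient lag-1 autoregressive coefficient in (-1, 1).
#' @param seed optional integer seed.
#' @return numeric vector of length `n_volumes`.
#' @export
synth_bold <- function(design, true_betas, noise_sd = 1,
                       ar_coefficient = 0.3, seed = NULL) {
  X <- design$X
  if (!is.null(names(true_betas)) && !is.null(colnames(X))) {
    if (!all(colnames(X) %in% names(true_betas)))
      stop("true_betas names do not cover design columns")
    true_betas <- true_betas[colnames(X)]
  }
  if (length(true_betas) != ncol(X))
    stop("beta vector length must match design columns")
  if (abs(ar_coefficient) >= 1) stop("ar_coefficient must lie in (-1, 1)")
  if (!is.null(seed)) set.seed(seed)
  mu <- as.numeric(X %*% true_betas)
  if (noise_sd == 0) return(mu)
  e <- rnorm(nrow(X), 0, noise_sd)
  noise <- as.numeric(stats::filter(e, ar_coefficient,
                                    method = "recursive"))
  mu + noise
}

#' Ordinary least-squares fit of a voxel time series
#'
#' Regresses the series on the design columns plus an intercept. With
#' noiseless data the true betas are recovered exactly (to numerical
#' precision).
#'
#' @param design a `design_matrix`.
#' @param series numeric vector of length `n_volumes`.
#' @return list with `betas`, `se`, `sigma2`, `df` (intercept excluded from
#'   `betas`).
#' @export
ols_fit <- function(design, series) {
  X <- design$X
  if (length(series) != nrow(X)) stop("series length must match n_volumes")
  if (nrow(X) <= ncol(X) + 1) stop("need more volumes than columns")
  qrX <- qr(cbind(intercept = 1, X))
  if (qrX$rank < ncol(X) + 1) stop("rank-deficient design")
  fit <- lm(series ~ X)
  cf <- coef(fit)
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  names(cf) <- names(se) <- c("intercept", colnames(X))
  list(betas = cf[-1], se = se[-1],
       sigma2 = sum(fit$residuals^2) / fit$df.residual,
       df = fit$df.residual)
}
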