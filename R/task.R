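#' Probabilistic reversal learning task configuration
#'
#' Defines the PRL task: 180 trials of two-alternative choice under a 1 s
#' response deadline, probabilistic and asymmetric feedback (+/-
#' `feedback_magnitude` points), and performance-triggered contingency
#' reversals. After `reversal_criterion_k` consecutive choices of the
#' currently high-probability stimulus, a uniformly drawn number of buffer
#' trials (inclusive range `buffer_trials`) is appended before the reversal
#' fires, so the criterion cannot be inferred from a fixed run length.
#'
#' @param n_trials number of trials (default 180).
#' @param p_high probability of positive feedback for the high-probability
#'   stimulus; must satisfy `0.5 < p_high <= 1`.
#' @param p_low probability of positive feedback for the other stimulus;
#'   `0 <= p_low < p_high`.
#' @param feedback_magnitude points per outcome (outcomes are +/- this value).
#' @param reversal_criterion_k consecutive correct choices that arm a
#'   reversal.
#' @param buffer_trials integer length-2 inclusive range of buffer trials.
#' @param response_deadline seconds available to respond.
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_trials = 180, p_high = 0.70, p_low = 0.30,
                        feedback_magnitude = 10, reversal_criterion_k = 5,
                        buffer_trials = c(1, 4), response_deadline = 1.0) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  if (!(p_high > 0.5 && p_high <= 1)) stop("p_high must lie in (0.5, 1]")
  if (!(p_low >= 0 && p_low < p_high)) stop("p_low must lie in [0, p_high)")
  if (reversal_criterion_k < 1) stop("reversal_criterion_k must be >= 1")
  buffer_trials <- as.integer(buffer_trials)
  if (length(buffer_trials) != 2 || any(buffer_trials < 0) ||
      buffer_trials[1] > buffer_trials[2])
    stop("buffer_trials must be a nonnegative inclusive range")
  if (response_deadline <= 0) stop("response_deadline must be positive")
  structure(list(n_trials = as.integer(n_trials), p_high = p_high,
                 p_low = p_low, feedback_magnitude = feedback_magnitude,
                 reversal_criterion_k = as.integer(reversal_criterion_k),
                 buffer_trials = buffer_trials,
                 response_deadline = response_deadline),
            class = "task_config")
}

# Event timing within a trial (seconds), used to lay trials on the scanner
# clock: fixation jitter 1-4 s, stimulus 1.25 s, ISI jitter 1-4 s, outcome
# 0.65 s.
.trial_timing <- list(fix_range = c(1, 4), stim_dur = 1.25,
                      isi_range = c(1, 4), outcome_dur = 0.65)

#' Simulate one RLDDM agent on the PRL task
#'
#' Forward-simulates the hybrid model: on each trial the drift rate is
#' `kappa * (Q_chosen_candidate difference)`, the bounded accumulator is run
#' by Euler-Maruyama at step `dt`, and the Q value of the chosen stimulus is
#' updated by the Rescorla-Wagner rule from unit-scaled feedback. Paths not
#' absorbed within `response_deadline - ndt` are late trials: no choice or
#' feedback is recorded and no learning occurs. Event onsets on a session
#' clock (decision and outcome phases, with jittered fixation and ISI) are
#' attached for first-level design construction.
#'
#' @param params an [rlddm_params] object.
#' @param config a [task_config] object.
#' @param seed integer seed; identical seeds give identical datasets.
#' @param dt Euler step for the within-trial diffusion (seconds).
#' @param subject_id,session identifiers stored in the dataset.
#' @return an object of class `subject_dataset`: list with `subject_id`,
#'   `session`, `trials` (data.frame, one row per trial) and clinical slots
#'   (NA here; filled by [generate_cohort()]).
#' @export
simulate_agent <- function(params, config = task_config(), seed = 1,
                           dt = 1e-3, subject_id = "s01", session = "pre") {
  stopifnot(inherits(params, "rlddm_params"), inherits(config, "task_config"))
  if (config$response_deadline <= params$ndt)
    stop("response deadline must exceed the non-decision time ",
         "(every trial would be late)")
  set.seed(seed)
  sim <- simulate_agent_cpp(config$n_trials, config$p_high, config$p_low,
                            config$reversal_criterion_k,
                            config$buffer_trials[1], config$buffer_trials[2],
                            config$response_deadline, params$kappa, params$a,
                            params$alpha, params$ndt, dt)
  n <- config$n_trials
  fix <- runif(n, .trial_timing$fix_range[1], .trial_timing$fix_range[2])
  isi <- runif(n, .trial_timing$isi_range[1], .trial_timing$isi_range[2])
  trial_len <- fix + .trial_timing$stim_dur + isi + .trial_timing$outcome_dur
  trial_start <- cumsum(c(0, trial_len[-n]))
  onset_dec <- trial_start + fix
  onset_out <- onset_dec + .trial_timing$stim_dur + isi

  trials <- data.frame(
    trial = seq_len(n) - 1L,
    high_prob_stim = sim$high_prob_stim,
    chosen_stim = sim$chosen_stim,
    rt = sim$rt,
    accuracy = ifelse(is.na(sim$chosen_stim), NA_integer_,
                      as.integer(sim$chosen_stim == sim$high_prob_stim)),
    feedback = sim$feedback_unit * config$feedback_magnitude,
    late = as.logical(sim$late),
    reversal_onset = sim$reversal_onset,
    onset_dec = onset_dec,
    onset_out = onset_out)
  structure(list(subject_id = subject_id, session = session, trials = trials,
                 pre_bdi = NA_real_, post_bdi = NA_real_, completed = NA,
                 group = NA_character_, true_params = params,
                 true_ea_beta = NA_real_),
            class = "subject_dataset")
}

#' Treatment-response labelling rule
#'
#' A subject is a responder iff they completed the intervention and their
#' post-treatment BDI-II score is at most half the pre-treatment score
#' (>= 50 percent symptom reduction). Noncompletion counts as treatment
#' failure regardless of scores.
#'
#' @param pre_bdi pre-treatment BDI-II score(s), > 0.
#' @param post_bdi post-treatment score(s); may be NA for noncompleters.
#' @param completed logical completion flag(s).
#' @return character vector, "responder" or "nonresponder".
#' @examples
#' classify_response(30, 15, TRUE)  # responder (boundary case)
#' classify_response(30, 16, TRUE)  # nonresponder
#' classify_response(30, NA, FALSE) # nonresponder
#' @export
classify_response <- function(pre_bdi, post_bdi, completed) {
  if (any(pre_bdi <= 0)) stop("pre_bdi must be positive")
  if (any(!is.na(post_bdi) & post_bdi < 0)) stop("post_bdi must be nonnegative")
  if (any(completed & is.na(post_bdi)))
    stop("completers must have a post_bdi score")
  ifelse(completed & post_bdi <= 0.5 * pre_bdi, "responder", "nonresponder")
}

#' Synthetic-cohort specification
#'
#' Generating distributions for a two-group (responder / nonresponder)
#' cohort. RLDDM parameters are drawn per subject in unconstrained space
#' (`log kappa, log a, logit alpha, logit(ndt/ndt_upper)`) and mapped to
#' native space. By default the two groups share identical behavioural
#' parameter distributions (a between-group null in behaviour) while the
#' neural scaling coefficient of the integrated-evidence regressor
#' (`ea_beta`) differs: responders carry the weaker accumulator signature.
#' Pre-treatment BDI-II is drawn per group (higher in nonresponders); the
#' post score is a group-specific fraction of the pre score plus truncated
#' noise, so derived response labels match the generating group. A fraction
#' of nonresponders drop out (no post score, completion flag off).
#'
#' @param n_responders,n_nonresponders group sizes (defaults 19 and 18).
#' @param param_means,param_sds length-4 unconstrained-space means and SDs
#'   for (kappa, a, alpha, ndt), shared by both groups unless
#'   `param_means_nonresp` is given.
#' @param param_means_nonresp optional distinct nonresponder means (used to
#'   inject a behavioural group difference; NULL keeps the behavioural null).
#' @param ndt_upper generator-space upper bound for the non-decision time (s).
#' @param ea_beta_means named length-2 vector of true EA-regressor betas
#'   (responder, nonresponder) in BOLD units.
#' @param ea_beta_sd between-subject SD of the EA beta.
#' @param pre_bdi_means,pre_bdi_sd group means (responder, nonresponder) and
#'   common SD of pre-treatment BDI-II.
#' @param post_frac_means,post_frac_sd mean post/pre score fraction per group
#'   and its SD; responder draws are truncated below 0.5, nonresponder draws
#'   above 0.5, keeping derived labels consistent with the generating group.
#' @param dropout_rate probability that a nonresponder drops out (11 of 18
#'   in the reference cohort).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_responders = 19, n_nonresponders = 18,
                        param_means = c(log(3), log(1.3), qlogis(0.30),
                                        qlogis(0.30 / 0.5)),
                        param_sds = c(0.25, 0.15, 0.50, 0.30),
                        param_means_nonresp = NULL,
                        ndt_upper = 0.5,
                        ea_beta_means = c(responder = 1, nonresponder = 3),
                        ea_beta_sd = 1.0,
                        pre_bdi_means = c(responder = 25, nonresponder = 32),
                        pre_bdi_sd = 7,
                        post_frac_means = c(responder = 0.35,
                                            nonresponder = 0.85),
                        post_frac_sd = 0.08,
                        dropout_rate = 11 / 18) {
  if (n_responders < 1 || n_nonresponders < 1) stop("both groups must be nonempty")
  if (any(param_sds < 0) || ea_beta_sd < 0 || pre_bdi_sd < 0 ||
      post_frac_sd < 0) stop("SDs must be nonnegative")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop("dropout_rate must lie in [0, 1]")
  stopifnot(length(param_means) == 4, length(param_sds) == 4)
  structure(list(n_responders = as.integer(n_responders),
                 n_nonresponders = as.integer(n_nonresponders),
                 param_means = param_means, param_sds = param_sds,
                 param_means_nonresp = param_means_nonresp,
                 ndt_upper = ndt_upper, ea_beta_means = ea_beta_means,
                 ea_beta_sd = ea_beta_sd, pre_bdi_means = pre_bdi_means,
                 pre_bdi_sd = pre_bdi_sd, post_frac_means = post_frac_means,
                 post_frac_sd = post_frac_sd, dropout_rate = dropout_rate),
            class = "cohort_spec")
}

# normal draw truncated to an interval by repeated sampling
.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic two-group cohort
#'
#' Draws subject-level RLDDM parameters, EA betas and clinical scores per
#' [cohort_spec()], simulates each subject on the task, derives response
#' labels with [classify_response()], and returns the datasets together with
#' a ground-truth table. Per-subject simulation seeds are derived from the
#' master seed by a fixed offset, so `(spec, config, seed)` fully determine
#' the cohort.
#'
#' @param spec a [cohort_spec] object.
#' @param config a [task_config] object.
#' @param seed master integer seed.
#' @param dt Euler step for within-trial simulation.
#' @return list with `subjects` (list of `subject_dataset`) and
#'   `ground_truth` (data.frame of native-space parameters, EA beta, clinical
#'   scores, labels and per-subject seeds).
#' @export
generate_cohort <- function(spec = cohort_spec(), config = task_config(),
                            seed = 1, dt = 1e-3) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "task_config"))
  n_r <- spec$n_responders
  n_n <- spec$n_nonresponders
  n <- n_r + n_n
  gen_group <- rep(c("responder", "nonresponder"), c(n_r, n_n))

  set.seed(seed)
  theta <- matrix(NA_real_, n, 4)
  for (j in 1:4) {
    mu <- rep(spec$param_means[j], n)
    if (!is.null(spec$param_means_nonresp))
      mu[gen_group == "nonresponder"] <- spec$param_means_nonresp[j]
    theta[, j] <- rnorm(n, mu, spec$param_sds[j])
  }
  ea_beta <- rnorm(n, spec$ea_beta_means[gen_group], spec$ea_beta_sd)
  pre_bdi <- pmax(.rnorm_trunc(n, spec$pre_bdi_means[gen_group],
                               spec$pre_bdi_sd, 5, 60), 5)
  frac <- numeric(n)
  is_r <- gen_group == "responder"
  frac[is_r] <- .rnorm_trunc(sum(is_r), spec$post_frac_means["responder"],
                             spec$post_frac_sd, 0.02, 0.5)
  frac[!is_r] <- .rnorm_trunc(sum(!is_r),
                              spec$post_frac_means["nonresponder"],
                              spec$post_frac_sd, 0.52, 1.2)
  post_bdi <- round(frac * pre_bdi, 1)
  completed <- rep(TRUE, n)
  completed[!is_r] <- runif(sum(!is_r)) >= spec$dropout_rate
  post_bdi[!completed] <- NA_real_
  subject_seed <- seed + 101L * seq_len(n)

  group <- classify_response(pre_bdi, post_bdi, completed)
  ids <- sprintf("s%02d", seq_len(n))
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    pars <- params_from_unconstrained(theta[i, ], spec$ndt_upper)
    sd_i <- simulate_agent(pars, config, seed = subject_seed[i], dt = dt,
                           subject_id = ids[i], session = "pre")
    sd_i$pre_bdi <- pre_bdi[i]
    sd_i$post_bdi <- post_bdi[i]
    sd_i$completed <- completed[i]
    sd_i$group <- group[i]
    sd_i$true_ea_beta <- ea_beta[i]
    subjects[[i]] <- sd_i
  }
  native <- t(vapply(seq_len(n), function(i) {
    p <- subjects[[i]]$true_params
    c(p$kappa, p$a, p$alpha, p$ndt)
  }, numeric(4)))
  ground_truth <- data.frame(
    subject_id = ids, gen_group = gen_group, group = group,
    kappa = native[, 1], a = native[, 2], alpha = native[, 3],
    ndt = native[, 4], true_ea_beta = ea_beta, pre_bdi = pre_bdi,
    post_bdi = post_bdi, completed = completed, seed = subject_seed)
  list(subjects = subjects, ground_truth = ground_truth)
}

.behaviour_cols <- c("subject_id", "session", "trial", "high_prob_stim",
                     "chosen_stim", "rt", "accuracy", "feedback", "late",
                     "reversal_onset", "onset_dec", "onset_out")

#' Read and write trial-level behaviour tables
#'
#' One CSV row per trial with columns `subject_id, session, trial,
#' high_prob_stim, chosen_stim, rt, accuracy, feedback, late,
#' reversal_onset, onset_dec, onset_out`. `write_behaviour` followed by
#' `read_behaviour` is the identity up to float round-trip. Malformed rows
#' (an RT outside `(0, deadline]` on a non-late trial, or late trials
#' carrying a choice/feedback) are rejected with their row numbers.
#'
#' @param datasets list of `subject_dataset` objects (or a cohort's
#'   `subjects` element).
#' @param path CSV file path.
#' @param deadline response deadline used to validate RTs on read.
#' @return `read_behaviour` returns a list of `subject_dataset` objects
#'   (clinical slots NA); `write_behaviour` returns `path` invisibly.
#' @export
write_behaviour <- function(datasets, path) {
  tabs <- lapply(datasets, function(d) {
    cbind(subject_id = d$subject_id, session = d$session, d$trials)
  })
  tab <- do.call(rbind, tabs)
  write.csv(tab[, .behaviour_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behaviour
#' @export
read_behaviour <- function(path, deadline = 1.0) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.behaviour_cols, names(tab))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(tab) == 0) stop("empty behaviour table")
  tab$late <- as.logical(tab$late)
  bad_rt <- which(!tab$late & (is.na(tab$rt) | tab$rt <= 0 |
                                 tab$rt > deadline))
  if (length(bad_rt) > 0)
    stop("rt outside (0, ", deadline, "] on non-late row(s): ",
         paste(bad_rt, collapse = ", "))
  bad_late <- which(tab$late & (!is.na(tab$chosen_stim) | !is.na(tab$rt) |
                                  !is.na(tab$feedback)))
  if (length(bad_late) > 0)
    stop("late row(s) carry choice/rt/feedback: ",
         paste(bad_late, collapse = ", "))
  split_keys <- unique(tab[, c("subject_id", "session")])
  out <- vector("list", nrow(split_keys))
  for (i in seq_len(nrow(split_keys))) {
    sel <- tab$subject_id == split_keys$subject_id[i] &
      tab$session == split_keys$session[i]
    trials <- tab[sel, setdiff(.behaviour_cols, c("subject_id", "session"))]
    if (nrow(trials) == 0) stop("empty trial section for subject ",
                                split_keys$subject_id[i])
    trials <- trials[order(trials$trial), ]
    if (!identical(as.integer(trials$trial),
                   seq_len(nrow(trials)) - 1L))
      stop("trial indices of subject ", split_keys$subject_id[i],
           " are not 0..n-1 without gaps")
    rownames(trials) <- NULL
    out[[i]] <- structure(
      list(subject_id = split_keys$subject_id[i],
           session = split_keys$session[i], trials = trials,
           pre_bdi = NA_real_, post_bdi = NA_real_, completed = NA,
           group = NA_character_, true_params = NULL,
           true_ea_beta = NA_real_),
      class = "subject_dataset")
  }
  out
}

#' Read and write per-subject clinical tables
#'
#' Columns: `subject_id, pre_bdi, post_bdi, completed, group`. On read the
#' group label is recomputed from the scores and completion flag and checked
#' against the stored label.
#'
#' @param ground_truth a cohort's ground-truth data.frame (or any data.frame
#'   with the clinical columns).
#' @param path CSV file path.
#' @return `read_clinical` returns the validated data.frame.
#' @export
write_clinical <- function(ground_truth, path) {
  write.csv(ground_truth[, c("subject_id", "pre_bdi", "post_bdi",
                             "completed", "group")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "pre_bdi", "post_bdi", "completed", "group")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  relab <- classify_response(tab$pre_bdi, tab$post_bdi, tab$completed)
  if (!identical(relab, tab$group))
    stop("stored group labels disagree with the labelling rule")
  tab
}

#' Overall response and completion rates
#'
#' Simple cohort summaries: the response rate is the percentage of recruited
#' subjects labelled responders; the completion rate is the percentage with
#' the completion flag set.
#'
#' @param group character vector of labels ("responder"/"nonresponder").
#' @param completed logical completion flags.
#' @return named list with `response_rate_pct` and `completion_rate_pct`.
#' @export
cohort_rates <- function(group, completed) {
  list(response_rate_pct = 100 * mean(group == "responder"),
       completion_rate_pct = 100 * mean(completed))
}
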