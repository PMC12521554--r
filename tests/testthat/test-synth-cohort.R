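# Task generator, agent simulation, cohort assembly, response labelling,
# behaviour CSV round-trips.

test_that("task_config validates the schedule", {
  expect_error(task_config(p_high = 0.4), "p_high")
  expect_error(task_config(p_low = 0.9), "p_low")
  expect_error(task_config(buffer_trials = c(3, 1)), "range")
  expect_equal(task_config()$n_trials, 180L)
})

test_that("a simulated agent produces a complete, consistent dataset", {
  d <- simulate_agent(typical_params(), task_config(), seed = 3)
  tr <- d$trials
  expect_equal(nrow(tr), 180)
  expect_identical(tr$trial, 0:179)
  # rt/choice/feedback present iff the trial is not late
  expect_true(all(is.na(tr$rt[tr$late])))
  expect_true(all(is.na(tr$chosen_stim[tr$late])))
  expect_true(all(is.na(tr$feedback[tr$late])))
  ok <- !tr$late
  expect_true(all(tr$rt[ok] > 0 & tr$rt[ok] <= 1))
  expect_true(all(tr$feedback[ok] %in% c(-10, 10)))
  expect_true(all(tr$accuracy[ok] ==
                    (tr$chosen_stim[ok] == tr$high_prob_stim[ok])))
  # onsets advance monotonically and outcome follows decision
  expect_true(all(diff(tr$onset_dec) > 0))
  expect_true(all(tr$onset_out > tr$onset_dec))
})

test_that("identical seeds reproduce the dataset exactly", {
  d1 <- simulate_agent(typical_params(), task_config(), seed = 9)
  d2 <- simulate_agent(typical_params(), task_config(), seed = 9)
  expect_identical(d1$trials, d2$trials)
})

test_that("simulation rejects a deadline shorter than the non-decision time", {
  p <- rlddm_params(3, 1.3, 0.3, 0.9)
  expect_error(simulate_agent(p, task_config(response_deadline = 0.8)),
               "deadline")
})

test_that("reversals respect the learning criterion plus minimum buffer", {
  cfg <- task_config()
  k_min <- cfg$reversal_criterion_k + cfg$buffer_trials[1]
  for (s in 1:10) {
    tr <- simulate_agent(typical_params(), cfg, seed = 100 + s)$trials
    onsets <- which(tr$reversal_onset == 1)
    if (length(onsets) > 1) expect_true(all(diff(onsets) >= k_min))
  }
})

test_that("zero learning gives chance accuracy; learning beats chance", {
  accs0 <- accs1 <- numeric(50)
  p0 <- rlddm_params(3, 1.3, 1e-9, 0.3)  # effectively alpha = 0: no learning
  p1 <- rlddm_params(3, 2, 0.3, 0.3)
  cfg1 <- task_config(p_high = 0.8, p_low = 0.2)
  for (s in 1:50) {
    t0 <- simulate_agent(p0, task_config(), seed = 500 + s)$trials
    accs0[s] <- mean(t0$accuracy[!t0$late])
    t1 <- simulate_agent(p1, cfg1, seed = 700 + s)$trials
    accs1[s] <- mean(t1$accuracy[!t1$late])
  }
  se0 <- sqrt(0.25 / (50 * 180))
  expect_lt(abs(mean(accs0) - 0.5), 3 * se0 + 0.01)
  expect_gt(mean(accs1), 0.5 + 3 * sd(accs1) / sqrt(50))
})

test_that("response labelling implements the 50 percent reduction rule", {
  expect_equal(classify_response(30, 15, TRUE), "responder")
  expect_equal(classify_response(30, 16, TRUE), "nonresponder")
  expect_equal(classify_response(30, NA, FALSE), "nonresponder")
  expect_equal(classify_response(30, 5, FALSE), "nonresponder")
  expect_error(classify_response(-2, 1, TRUE), "positive")
})

test_that("generated cohorts respect the spec and derive labels correctly", {
  spec <- cohort_spec(n_responders = 5, n_nonresponders = 5,
                      dropout_rate = 0)
  coh <- generate_cohort(spec, short_task(), seed = 4)
  gt <- coh$ground_truth
  expect_equal(nrow(gt), 10)
  expect_true(all(!is.na(gt$post_bdi)))  # no dropouts
  expect_identical(classify_response(gt$pre_bdi, gt$post_bdi, gt$completed),
                   gt$group)
  expect_identical(gt$gen_group, gt$group)  # truncated rules keep labels
  # determinism
  coh2 <- generate_cohort(spec, short_task(), seed = 4)
  expect_identical(coh$ground_truth, coh2$ground_truth)
  expect_identical(coh$subjects[[3]]$trials, coh2$subjects[[3]]$trials)
  expect_error(cohort_spec(n_responders = 0), "nonempty")
})

test_that("behavioural null cohorts show no systematic group differences", {
  # identical parameter distributions: two-sample tests on native parameters
  # and accuracy should reject at close to the nominal rate
  spec <- cohort_spec(n_responders = 10, n_nonresponders = 10,
                      dropout_rate = 0.3)
  n_draws <- 60
  p_param <- matrix(NA_real_, n_draws, 4)
  p_acc <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    coh <- generate_cohort(spec, short_task(40), seed = 2000 + i)
    gt <- coh$ground_truth
    acc <- vapply(coh$subjects, function(s) {
      tr <- s$trials
      mean(tr$accuracy[!tr$late])
    }, numeric(1))
    for (j in 1:4)
      p_param[i, j] <- t.test(gt[[c("kappa", "a", "alpha", "ndt")[j]]] ~
                                gt$gen_group)$p.value
    p_acc[i] <- t.test(acc ~ gt$gen_group)$p.value
  }
  # nonsignificant in >= 90% of draws, and type-I error near alpha
  expect_gte(mean(apply(p_param, 2, function(p) mean(p > 0.05))), 0.9)
  expect_lt(abs(mean(p_acc < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / n_draws) + 0.02)
})

test_that("behaviour tables round-trip through CSV", {
  spec <- cohort_spec(n_responders = 2, n_nonresponders = 1)
  coh <- generate_cohort(spec, short_task(), seed = 6)
  path <- tempfile(fileext = ".csv")
  write_behaviour(coh$subjects, path)
  back <- read_behaviour(path, deadline = 1.0)
  expect_equal(length(back), 3)
  for (i in 1:3) {
    orig <- coh$subjects[[i]]$trials
    expect_equal(back[[i]]$trials, orig, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(back[[i]]$subject_id, coh$subjects[[i]]$subject_id)
  }
  unlink(path)
})

test_that("malformed behaviour files are rejected with row numbers", {
  spec <- cohort_spec(n_responders = 2, n_nonresponders = 1)
  coh <- generate_cohort(spec, short_task(), seed = 6)
  path <- tempfile(fileext = ".csv")
  write_behaviour(coh$subjects, path)
  tab <- read.csv(path)
  bad <- which(!tab$late)[1]
  tab$rt[bad] <- 1.7
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_behaviour(path, deadline = 1.0), as.character(bad))
  # empty trial section
  write.csv(tab[0, ], path, row.names = FALSE)
  expect_error(read_behaviour(path), "empty")
  # missing mandatory column
  write.csv(tab[, -3], path, row.names = FALSE)
  expect_error(read_behaviour(path), "missing mandatory column")
  unlink(path)
})

test_that("clinical tables round-trip and labels are re-validated", {
  spec <- cohort_spec(n_responders = 3, n_nonresponders = 3)
  coh <- generate_cohort(spec, short_task(), seed = 8)
  path <- tempfile(fileext = ".csv")
  write_clinical(coh$ground_truth, path)
  back <- read_clinical(path)
  expect_equal(back$pre_bdi, coh$ground_truth$pre_bdi)
  tab <- read.csv(path)
  tab$group[1] <- setdiff(c("responder", "nonresponder"), tab$group[1])
  write.csv(tab, path, row.names = FALSE)
  expect_error(read_clinical(path), "disagree")
  unlink(path)
})

test_that("cohort rates reproduce simple proportions", {
  g <- rep(c("responder", "nonresponder"), c(19, 18))
  comp <- rep(c(TRUE, FALSE), c(26, 11))
  r <- cohort_rates(g, comp)
  expect_equal(r$response_rate_pct, 100 * 19 / 37)
  expect_equal(r$completion_rate_pct, 100 * 26 / 37)
})
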