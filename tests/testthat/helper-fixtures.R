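# Shared fixtures: a typical agent parameterisation and a small task for
# fast tests. Everything is generated in code; no stored data.

typical_params <- function() rlddm_params(kappa = 3, a = 1.3, alpha = 0.3,
                                          ndt = 0.3)

short_task <- function(n_trials = 60) task_config(n_trials = n_trials)

# a fitted small cohort reused by design/pipeline tests
small_fitted_subject <- function(seed = 2) {
  d <- simulate_agent(typical_params(), task_config(), seed = seed)
  f <- fit_subject(d, fit_config(n_restarts = 3), seed = seed)
  list(dataset = d, fit = f)
}
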