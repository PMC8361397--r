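# Shared fixtures, built in code. Heavy objects are memoized so several
# test files can reuse one small hierarchical fit.

fixture_env <- new.env(parent = emptyenv())

# A single-group cohort and a short two-chain fit of the full (v+a) model,
# small enough to run in seconds but large enough for posterior machinery
# (DIC, PPC, reconstruction) to be exercised meaningfully.
small_fit <- function() {
  if (is.null(fixture_env$small_fit)) {
    coh <- generate_cohort(default_group_specs()["Control"], 4,
                           schedule_config(n_runs = 5), seed = 42,
                           dt = 1e-3)
    filt <- run_inclusion_filters(coh$trials)
    model <- build_model(ddm_model_spec(varies = c("v", "a")), filt$trials)
    fit <- sample_posterior(model, mcmc_config(n_samples = 900,
                                               n_burn_in = 400, seed = 5))
    fixture_env$small_fit <- list(cohort = coh, fit = fit, model = model)
  }
  fixture_env$small_fit
}

# Hand-built trial table with known structure for filter/likelihood tests.
toy_trials <- function(n_per_cond = 4, subjects = c("s1", "s2"),
                       group = "G", rt0 = 0.8) {
  purrr::map_dfr(subjects, function(sid) {
    tibble::tibble(
      subject_id = sid, group = group, run = 5,
      trial_index = seq_len(3 * n_per_cond),
      condition = factor(rep(ant_conditions, each = n_per_cond),
                         levels = ant_conditions),
      response = rep(c(1L, 1L, 1L, 0L), length.out = 3 * n_per_cond),
      rt = rt0 + seq(0, 0.5, length.out = 3 * n_per_cond),
      missed = FALSE
    )
  })
}
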