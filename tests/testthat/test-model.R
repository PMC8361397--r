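# Model graph construction and likelihood assembly.

test_that("condition effects exist only for parameters declared to vary", {
  d <- toy_trials()
  m1 <- build_model(ddm_model_spec(varies = "v"), d)
  eff1 <- m1$params[m1$params$role == "cond_effect", ]
  expect_true(all(eff1$param == "v"))
  expect_equal(nrow(eff1), 2)  # EASY + HARD for one group
  m3 <- build_model(ddm_model_spec(varies = c("v", "a")), d)
  # the full model adds exactly the boundary condition effects
  expect_equal(nrow(m3$params), nrow(m1$params) + 2)
  expect_error(ddm_model_spec(varies = "t0"), "subset")
})

test_that("one subject in one condition yields the minimal graph", {
  d <- tibble::tibble(
    subject_id = "s1", group = "G", run = 5, trial_index = 1:8,
    condition = factor("congruent", levels = ant_conditions),
    response = rep(c(1L, 0L), 4), rt = seq(0.5, 1.2, length.out = 8)
  )
  m <- build_model(ddm_model_spec(varies = c("v", "a")), d)
  expect_setequal(
    m$params$name,
    c("mu_v[G]", "sigma_v[G]", "mu_a[G]", "sigma_a[G]", "mu_t0[G]",
      "sigma_t0[G]", "v[s1]", "a[s1]", "t0[s1]")
  )
})

test_that("the total likelihood is an exchangeable sum of trial densities", {
  d <- toy_trials(n_per_cond = 2, subjects = "s1")
  spec <- ddm_model_spec(varies = c("v", "a"), p_outlier = 0.05)
  m <- build_model(spec, d)
  theta <- c(
    "mu_v[G]" = 2, "sigma_v[G]" = 0.3, "mu_a[G]" = 1.5,
    "sigma_a[G]" = 0.2, "mu_t0[G]" = 0.3, "sigma_t0[G]" = 0.05,
    "b_v[incongruent_easy,G]" = -0.4, "b_v[incongruent_hard,G]" = -0.7,
    "b_a[incongruent_easy,G]" = 0.1, "b_a[incongruent_hard,G]" = 0.2,
    "v[s1]" = 1.8, "a[s1]" = 1.6, "t0[s1]" = 0.35
  )
  # term-by-term oracle: resolve each trial's (v, a) and sum densities
  eff_v <- c(congruent = 0, incongruent_easy = -0.4,
             incongruent_hard = -0.7)
  eff_a <- c(congruent = 0, incongruent_easy = 0.1, incongruent_hard = 0.2)
  manual <- sum(vapply(seq_len(nrow(d)), function(i) {
    cc <- as.character(d$condition[i])
    p <- ddm_params(v = 1.8 + eff_v[[cc]], a = 1.6 + eff_a[[cc]],
                    t0 = 0.35, p_outlier = 0.05, rt_max = 3)
    wfpt_log_density(d$rt[i], d$response[i], p)
  }, numeric(1)))
  expect_equal(log_likelihood(m, theta), manual, tolerance = 1e-10)
  # permutation invariance
  dp <- d[sample(nrow(d)), ]
  mp <- build_model(spec, dp)
  expect_equal(log_likelihood(mp, theta), manual, tolerance = 1e-10)
  # a single trial reduces to its own density
  m1 <- build_model(ddm_model_spec(varies = character(), p_outlier = 0.05),
                    d[1, ])
  th1 <- c("mu_v[G]" = 2, "sigma_v[G]" = 0.3, "mu_a[G]" = 1.5,
           "sigma_a[G]" = 0.2, "mu_t0[G]" = 0.3, "sigma_t0[G]" = 0.05,
           "v[s1]" = 1.8, "a[s1]" = 1.6, "t0[s1]" = 0.35)
  expect_equal(
    log_likelihood(m1, th1),
    wfpt_log_density(d$rt[1], d$response[1],
                     ddm_params(v = 1.8, a = 1.6, t0 = 0.35,
                                p_outlier = 0.05, rt_max = 3)),
    tolerance = 1e-10
  )
})

test_that("covariates shift drift linearly in the likelihood", {
  d <- toy_trials(n_per_cond = 2, subjects = "s1")
  d$beta_net <- seq(-1, 1, length.out = nrow(d))
  spec <- ddm_model_spec(varies = character(), covariates = "beta_net",
                         p_outlier = 0.05)
  m <- build_model(spec, d)
  base <- c("mu_v[G]" = 2, "sigma_v[G]" = 0.3, "mu_a[G]" = 1.5,
            "sigma_a[G]" = 0.2, "mu_t0[G]" = 0.3, "sigma_t0[G]" = 0.05,
            "v[s1]" = 1.5, "a[s1]" = 1.6, "t0[s1]" = 0.35)
  theta <- c(base, "b_beta_net[G]" = 0.6)
  manual <- sum(vapply(seq_len(nrow(d)), function(i) {
    p <- ddm_params(v = 1.5 + 0.6 * d$beta_net[i], a = 1.6, t0 = 0.35,
                    p_outlier = 0.05, rt_max = 3)
    wfpt_log_density(d$rt[i], d$response[i], p)
  }, numeric(1)))
  expect_equal(log_likelihood(m, theta), manual, tolerance = 1e-10)
})

test_that("schema violations are rejected", {
  d <- toy_trials()
  expect_error(build_model(ddm_model_spec(), d[0, ]), "empty")
  dna <- d
  dna$rt[1] <- NA
  expect_error(build_model(ddm_model_spec(), dna), "missed")
  expect_error(build_model(ddm_model_spec(covariates = "nope"), d),
               "not found")
  dbad <- d
  dbad$condition <- as.character(dbad$condition)
  dbad$condition[1] <- "neutral"
  expect_error(build_model(ddm_model_spec(), dbad), "Unknown conditions")
  # a subject lacking one represented condition
  dmiss <- d[!(d$subject_id == "s2" & d$condition == "incongruent_hard"), ]
  expect_error(build_model(ddm_model_spec(), dmiss), "each represented")
})
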