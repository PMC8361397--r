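# Sampler building blocks and diagnostics.

test_that("config invariants are enforced", {
  expect_error(mcmc_config(n_samples = 100, n_burn_in = 100), "n_samples")
  expect_error(mcmc_config(thin = 0), "thin")
  expect_error(mcmc_config(n_chains = 1), "n_chains")
  pc <- study_mcmc_config()
  expect_equal(pc$n_samples, 95000L)
  expect_equal(pc$n_burn_in, 35000L)
  expect_equal(pc$thin, 5L)
})

test_that("the conjugate group-mean draw matches the closed-form posterior", {
  x <- withr::with_seed(1, rnorm(12, 2.5, 0.4))
  prior <- list(mean = 2, sd = 3, lower = -Inf, upper = Inf)
  sigma <- 0.4
  prec <- 1 / prior$sd^2 + length(x) / sigma^2
  m_exact <- (prior$mean / prior$sd^2 + sum(x) / sigma^2) / prec
  s_exact <- sqrt(1 / prec)
  draws <- withr::with_seed(2, replicate(20000, {
    antddm:::gibbs_mu_draw(x, sigma, prior)
  }))
  expect_lt(abs(mean(draws) - m_exact), 4 * s_exact / sqrt(20000))
  expect_lt(abs(sd(draws) - s_exact), 0.02 * s_exact)
  # truncation respected
  tr <- withr::with_seed(3, replicate(2000, {
    antddm:::gibbs_mu_draw(x, sigma, list(mean = 2, sd = 3, lower = 2.6,
                                          upper = 2.7))
  }))
  expect_true(all(tr >= 2.6 & tr <= 2.7))
})

test_that("identical seeds give identical chains", {
  sf <- small_fit()
  cfg <- mcmc_config(n_samples = 300, n_burn_in = 100, seed = 17)
  f1 <- sample_posterior(sf$model, cfg)
  f2 <- sample_posterior(sf$model, cfg)
  expect_identical(f1$draws, f2$draws)
  # chains with different seeds differ
  f3 <- sample_posterior(sf$model, mcmc_config(n_samples = 300,
                                               n_burn_in = 100, seed = 18))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("with an almost flat likelihood the posterior matches the prior", {
  # contaminant weight ~ 1 makes the data carry almost no information, so
  # the covariate coefficient posterior should reproduce its N(0, 1) prior
  d <- toy_trials(n_per_cond = 2, subjects = c("s1", "s2"))
  d$beta_net <- withr::with_seed(4, rnorm(nrow(d)))
  spec <- ddm_model_spec(varies = character(), covariates = "beta_net",
                         p_outlier = 0.99)
  m <- build_model(spec, d)
  fit <- sample_posterior(m, mcmc_config(n_samples = 6000,
                                         n_burn_in = 1000, thin = 2,
                                         seed = 9))
  draws <- do.call(rbind, fit$draws)[, "b_beta_net[G]"]
  ks <- stats::ks.test(draws[seq(1, length(draws), by = 10)],
                       "pnorm", 0, 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("split R-hat separates mixed from unmixed chains", {
  m1 <- withr::with_seed(5, matrix(rnorm(4000), ncol = 2,
                                   dimnames = list(NULL, c("x", "y"))))
  m2 <- withr::with_seed(6, matrix(rnorm(4000), ncol = 2,
                                   dimnames = list(NULL, c("x", "y"))))
  rh <- gelman_rubin(list(m1, m2))
  expect_true(all(abs(rh$rhat - 1) < 0.05))
  expect_false(any(rh$flagged))
  # a shifted chain inflates between-chain variance far past 1.1
  rh2 <- gelman_rubin(list(m1, m2 + 10))
  expect_true(all(rh2$rhat > 1.1))
  expect_true(all(rh2$flagged))
  # R-hat never falls below 1 beyond the small-sample floor
  expect_true(all(rh$rhat > sqrt(1 - 1 / nrow(m1) * 2)))
  # zero within-chain variance reports degenerate, not a crash
  mc <- matrix(1, nrow = 100, ncol = 1, dimnames = list(NULL, "c"))
  rh3 <- gelman_rubin(list(mc, mc))
  expect_true(rh3$degenerate)
})

test_that("condition posteriors reconstruct linearly from the draws", {
  sf <- small_fit()
  cp <- reconstruct_condition_posteriors(sf$fit)
  m <- sf$fit$draws[[1]]
  base <- m[, "mu_v[Control]"]
  cong <- cp$value[cp$chain == 1 & cp$parameter == "v" &
                     cp$condition == "congruent" & cp$group == "Control"]
  expect_identical(cong, unname(base))  # baseline draws, exactly
  easy <- cp$value[cp$chain == 1 & cp$parameter == "v" &
                     cp$condition == "incongruent_easy" &
                     cp$group == "Control"]
  expect_equal(easy, unname(base + m[, "b_v[incongruent_easy,Control]"]))
  expect_equal(mean(easy),
               mean(base) + mean(m[, "b_v[incongruent_easy,Control]"]))
})

test_that("subject-level estimates are shrunk toward the group mean", {
  sf <- small_fit()
  td <- tidy(sf$fit)
  mu_v <- td$estimate[td$term == "mu_v[Control]"]
  subs <- sf$model$subjects$subject_id
  # crude per-subject drift MLE proxy: fit each subject's posterior mean
  # must lie between the group mean and a no-pooling direction; we check
  # the weaker, robust property that the subject spread is smaller than
  # the spread of per-subject accuracy-implied extremes
  v_hat <- td$estimate[td$term %in% sprintf("v[%s]", subs)]
  expect_lt(max(abs(v_hat - mu_v)), 3 * td$estimate[td$term ==
                                                      "sigma_v[Control]"] + 1)
})

test_that("tidy and glance summarize a fit", {
  sf <- small_fit()
  td <- tidy(sf$fit)
  expect_true(all(c("term", "estimate", "std.error", "conf.low",
                    "conf.high", "rhat") %in% names(td)))
  expect_equal(nrow(td), nrow(sf$model$params))
  gl <- glance(sf$fit)
  expect_equal(gl$n_chains, 2L)
  expect_equal(gl$n_parameters, nrow(sf$model$params))
  expect_true(gl$n_draws >= 10)
})
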