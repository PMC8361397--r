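# Model comparison and Bayesian hypothesis-test statistics.

test_that("DIC components behave on degenerate and conjugate toy posteriors", {
  # point-mass posterior: pD = 0 and DIC = -2 log L
  res <- antddm:::dic_core(rep(12.3, 100), 12.3)
  expect_equal(res$p_d, 0)
  expect_equal(res$dic, 12.3)
  # normal mean with known variance: effective parameters ~ 1
  y <- withr::with_seed(1, rnorm(25, 1, 1))
  post_prec <- 1 / 100 + length(y)        # N(0, 10^2) prior, sigma = 1
  post_mean <- sum(y) / post_prec
  post_sd <- sqrt(1 / post_prec)
  th <- withr::with_seed(2, rnorm(40000, post_mean, post_sd))
  dev <- vapply(th, function(t) -2 * sum(dnorm(y, t, 1, log = TRUE)),
                numeric(1))
  res <- antddm:::dic_core(dev, -2 * sum(dnorm(y, mean(th), 1, log = TRUE)))
  expect_lt(abs(res$p_d - 1), 0.05)
})

test_that("DIC on a fitted model is finite and reports its parts", {
  sf <- small_fit()
  d <- dic(sf$fit, n_draws = 200)
  expect_true(is.finite(d$dic))
  expect_gt(d$p_d, 0)
  expect_equal(d$dic, d$mean_deviance + d$p_d)
})

test_that("posterior overlap matches normal-theory closed forms", {
  n <- 4e4
  a <- withr::with_seed(3, rnorm(n))
  b <- withr::with_seed(4, rnorm(n))
  same <- posterior_overlap(a, b)
  expect_lt(abs(same$P - 50), 2)
  expect_false(same$significant)
  far <- posterior_overlap(a, b + 10)
  expect_lt(far$P, 0.01)
  expect_true(far$significant)
  # A ~ N(0,1), B ~ N(2.326 sqrt(2), 1): P = 100 * Phi(-2.326) ~ 1.0
  shifted <- posterior_overlap(a, b + 2.326 * sqrt(2))
  expect_lt(abs(shifted$P - 100 * pnorm(-2.326)), 0.4)
  # symmetry (exact for equal-length draw sets)
  expect_equal(posterior_overlap(a, b + 1)$P, posterior_overlap(b + 1, a)$P)
  # density-overlap alternative is available and bounded
  dov <- posterior_overlap(a, b + 2.326 * sqrt(2), method = "density")
  expect_gt(dov$P, 0)
  expect_lt(dov$P, 50)
})

test_that("prob_nonzero reports tail mass and dominant sign", {
  expect_equal(prob_nonzero(c(1, 2, 3))$P, 100)
  expect_equal(prob_nonzero(c(1, 2, 3))$direction, "positive")
  n <- 2e5
  sym <- withr::with_seed(5, rnorm(n))
  expect_lt(abs(prob_nonzero(sym)$P - 50), 1)
  shifted <- prob_nonzero(sym + 1)         # N(1,1): P ~ 100 * Phi(1)
  expect_lt(abs(shifted$P - 100 * pnorm(1)), 1)
  expect_false(shifted$significant)
  flipped <- prob_nonzero(-(sym + 1))
  expect_equal(flipped$P, shifted$P)
  expect_equal(flipped$direction, "negative")
})

test_that("posterior predictive summaries are coherent and reproducible", {
  sf <- small_fit()
  ppc <- posterior_predictive(sf$fit, n_draws = 100, seed = 6, dt = 2e-3)
  s <- ppc$summary
  acc <- s[s$statistic == "accuracy", ]
  expect_true(all(acc$observed >= 0 & acc$observed <= 1))
  expect_true(all(acc$sim_mean >= 0 & acc$sim_mean <= 1))
  # RT quantiles increase with the quantile level in every cell
  qs <- s[grepl("^rt_q", s$statistic), ] |>
    dplyr::arrange(.data$group, .data$condition, .data$statistic) |>
    dplyr::group_by(.data$group, .data$condition) |>
    dplyr::summarise(mono_obs = all(diff(.data$observed) > 0),
                     mono_sim = all(diff(.data$sim_mean) > 0),
                     .groups = "drop")
  expect_true(all(qs$mono_obs))
  expect_true(all(qs$mono_sim))
  expect_true(all(s$percentile >= 0 & s$percentile <= 100))
  ppc2 <- posterior_predictive(sf$fit, n_draws = 100, seed = 6, dt = 2e-3)
  expect_identical(ppc$summary, ppc2$summary)
  expect_error(posterior_predictive(sf$fit, n_draws = 1e6), "exceeds")
})

test_that("the fitted model reproduces its own data in the predictive check", {
  sf <- small_fit()
  ppc <- posterior_predictive(sf$fit, n_draws = 150, seed = 7, dt = 2e-3)
  inside <- with(ppc$summary,
                 observed >= sim_q025 & observed <= sim_q975)
  expect_gte(mean(inside), 0.9)
})
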