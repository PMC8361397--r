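# Single-trial GLM: HRF shape, design layout, exact and noisy recovery,
# z-scoring, high-pass drift insensitivity.

make_run <- function(seed, amps = NULL, config = bold_run_config(),
                     run_id = 1) {
  ev <- generate_trial_schedule(schedule_config(n_runs = 5), seed = seed)
  ev <- ev[ev$run == run_id, ]
  if (is.null(amps)) amps <- withr::with_seed(seed + 1, rnorm(36, 0.8, 1))
  list(run = generate_bold_run(ev, amps, config, seed = seed + 2),
       amps = amps)
}

test_that("the canonical HRF is causal with a unit peak near 5 s", {
  tg <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1, tolerance = 1e-6)
  t_peak <- tg[which.max(h)]
  expect_gt(t_peak, 4)
  expect_lt(t_peak, 7)
  expect_gt(sum(h) * 0.01, 0)              # net positive response
  expect_lt(min(h), 0)                     # undershoot present
  expect_gt(tg[which.min(h)], 10)          # undershoot after the peak
})

test_that("the design has 36 trial columns, 6 motion columns and 4 cosines", {
  r <- make_run(1)
  des <- build_trial_design(r$run)
  expect_equal(sum(des$roles == "trial"), 36)
  expect_equal(sum(des$roles == "motion"), 6)
  expect_equal(sum(des$roles == "intercept"), 1)
  # floor(2 * 156 * 1.92 / 128) = 4 cosine columns for a 299.52 s run
  expect_equal(sum(des$roles == "cosine"), 4)
  dup <- r$run
  dup$events$target_onset[2] <- dup$events$target_onset[1]
  expect_error(build_trial_design(dup), "Duplicate")
})

test_that("noiseless runs are recovered at machine precision", {
  cfg <- bold_run_config(noise_sd = 0, drift_amplitude = 0, motion_leak = 0)
  r <- make_run(3, config = cfg)
  betas <- fit_beta_series(r$run, baseline = cfg$baseline)
  expect_equal(betas$beta, r$amps, tolerance = 1e-8)
})

test_that("a two-regressor toy design matches hand-computed normal equations", {
  x1 <- c(1, 0, 1, 0, 2, 0)
  x2 <- c(0, 1, 0, 2, 0, 1)
  y <- 2 * x1 + 1.5 * x2 + c(0.1, -0.1, 0.05, 0, -0.05, 0.02)
  X <- cbind(trial_01 = x1, trial_02 = x2)
  design <- structure(list(X = X, roles = c("trial", "trial"),
                           events = tibble::tibble(target_onset = c(1, 2))),
                      class = "trial_design")
  run <- list(bold = tibble::tibble(time = 0:5, bold = y))
  betas <- fit_beta_series(run, design, baseline = 1)
  # hand-solved normal equations on the same scaled series
  ys <- 100 * (y - 1)
  expected <- solve(crossprod(X), crossprod(X, ys))
  expect_equal(betas$beta, unname(drop(expected)), tolerance = 1e-10)
})

test_that("betas track true amplitudes at the default noise level", {
  for (seed in c(11, 12)) {
    r <- make_run(seed)
    betas <- fit_beta_series(r$run)
    expect_gte(cor(betas$beta, r$amps), 0.8)
  }
})

test_that("AR(1) prewhitening preserves recovery quality", {
  r <- make_run(21, config = bold_run_config(noise_ar = 0.5))
  plain <- fit_beta_series(r$run)
  white <- fit_beta_series(r$run, whiten = TRUE)
  expect_gte(cor(white$beta, r$amps), 0.75)
  expect_gt(attr(white, "ar1"), 0)
  expect_gt(cor(white$beta, plain$beta), 0.95)
})

test_that("the high-pass basis absorbs slow drift", {
  cfg0 <- bold_run_config(noise_sd = 0, drift_amplitude = 0,
                          motion_leak = 0)
  cfg1 <- bold_run_config(noise_sd = 0, drift_amplitude = 2,
                          drift_periods = 200, motion_leak = 0)
  amps <- withr::with_seed(31, rnorm(36, 0.8, 1))
  r0 <- make_run(30, amps = amps, config = cfg0)
  r1 <- make_run(30, amps = amps, config = cfg1)
  b0 <- fit_beta_series(r0$run, baseline = 100)
  b1 <- fit_beta_series(r1$run, baseline = 100)
  expect_equal(b1$beta, b0$beta, tolerance = 0.05)
})

test_that("z-scoring standardizes within scope and is affine-invariant", {
  b <- tibble::tibble(subject = rep(c("a", "b"), each = 20),
                      beta = withr::with_seed(41, rnorm(40, 3, 2)))
  z <- zscore_betas(b, by = "subject")
  stats <- z |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(m = mean(.data$beta), s = sd(.data$beta))
  expect_true(all(abs(stats$m) < 1e-12))
  expect_true(all(abs(stats$s - 1) < 1e-12))
  shifted <- b
  shifted$beta <- 5 * b$beta - 2
  expect_equal(zscore_betas(shifted, by = "subject")$beta, z$beta,
               tolerance = 1e-10)
  expect_error(zscore_betas(tibble::tibble(beta = rep(1, 5))), "variance")
  expect_error(zscore_betas(tibble::tibble(beta = 1)), ">= 2")
})
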