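# Synthetic cohort generator: degenerate variance, clinical RT ordering,
# covariate coupling, censoring.

test_that("zero between-subject SDs give identical subjects", {
  g <- group_spec("G", v = c(2, 1.6, 1.4), a = 1.8, t0 = 0.4,
                  sd_v = 0, sd_a = 0, sd_t0 = 0)
  coh <- generate_cohort(list(g), 4, schedule_config(n_runs = 5), seed = 1,
                         dt = 1e-3)
  expect_equal(length(unique(coh$subjects$v)), 1L)
  expect_equal(length(unique(coh$subjects$a)), 1L)
  expect_equal(length(unique(coh$subjects$t0)), 1L)
  expect_equal(coh$subjects$v[1], 2)
})

test_that("default cohort reproduces the clinical RT and accuracy ordering", {
  coh <- generate_cohort(default_group_specs(), 8,
                         schedule_config(n_runs = 5), seed = 7, dt = 1e-3)
  by_group <- coh$trials |>
    dplyr::filter(!.data$missed) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(rt = mean(.data$rt), acc = mean(.data$response))
  rt <- setNames(by_group$rt, by_group$group)
  acc <- setNames(by_group$acc, by_group$group)
  expect_true(rt[["Control"]] < rt[["AD"]])
  expect_true(rt[["AD"]] < rt[["LBD"]])
  expect_true(acc[["Control"]] > acc[["AD"]])
  expect_true(acc[["AD"]] > acc[["LBD"]])
  # right-skewed RT distributions with support above non-decision time
  sk <- coh$trials |>
    dplyr::filter(!.data$missed, !.data$outlier) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(skew = mean((.data$rt - mean(.data$rt))^3) /
                       sd(.data$rt)^3)
  expect_true(all(sk$skew > 0))
})

test_that("condition-invariant parameters give equal accuracies by condition", {
  g <- group_spec("G", v = 1.8, a = 1.8, t0 = 0.35, sd_v = 0.1,
                  sd_a = 0.1, sd_t0 = 0.02)
  coh <- generate_cohort(list(g), 10, schedule_config(n_runs = 6),
                         seed = 13, dt = 1e-3, p_outlier = 0)
  acc <- coh$trials |>
    dplyr::filter(!.data$missed) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(acc = mean(.data$response), n = dplyr::n())
  p0 <- mean(acc$acc)
  se <- sqrt(p0 * (1 - p0) / acc$n[1])
  expect_true(all(abs(acc$acc - p0) < 4 * se))
})

test_that("zero covariate coupling reproduces the uncoupled stream exactly", {
  p <- ddm_params(v = 1.5, a = 1.5, t0 = 0.3, p_outlier = 0.05)
  betas <- withr::with_seed(1, rnorm(200))
  coupled <- generate_coupled_trials(p, betas, b = 0, seed = 99, dt = 1e-3)
  plain <- simulate_trials(p, 200, seed = 99, dt = 1e-3)
  expect_identical(coupled[c("trial", "choice", "rt", "outlier")], plain)
})

test_that("positive coupling raises accuracy in high-covariate trials", {
  p <- ddm_params(v = 1.2, a = 1.5, t0 = 0.3)
  betas <- withr::with_seed(2, rnorm(8000))
  qs <- quantile(betas, c(0.25, 0.75))
  up <- generate_coupled_trials(p, betas, b = 0.5, seed = 3, dt = 1e-3)
  acc_top <- mean(up$choice[betas >= qs[2]])
  acc_bot <- mean(up$choice[betas <= qs[1]])
  expect_gt(acc_top, acc_bot)
  dn <- generate_coupled_trials(p, betas, b = -0.5, seed = 3, dt = 1e-3)
  expect_lt(mean(dn$choice[betas >= qs[2]]), mean(dn$choice[betas <= qs[1]]))
  expect_error(generate_coupled_trials(p, c(1, NA), b = 1), "finite")
})

test_that("slow trials are emitted as censored records", {
  g <- group_spec("Slow", v = 0.25, a = 3.2, t0 = 0.5, sd_v = 0.05,
                  sd_a = 0.05, sd_t0 = 0.01)
  coh <- generate_cohort(list(g), 3, schedule_config(n_runs = 5), seed = 5,
                         dt = 1e-3, p_outlier = 0)
  expect_gt(sum(coh$trials$missed), 0)
  expect_true(all(is.na(coh$trials$response[coh$trials$missed])))
  expect_true(all(is.na(coh$trials$rt[coh$trials$missed])))
  expect_true(all(coh$trials$rt[!coh$trials$missed] <= 3))
})

test_that("cohorts are reproducible from (config, seed)", {
  a <- generate_cohort(default_group_specs(), 2, schedule_config(n_runs = 5),
                       seed = 8, dt = 1e-3)
  b <- generate_cohort(default_group_specs(), 2, schedule_config(n_runs = 5),
                       seed = 8, dt = 1e-3)
  expect_identical(a$trials, b$trials)
  expect_identical(a$subjects, b$subjects)
})
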