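# D-bar / pD / DIC from deviance draws and the deviance at the posterior
# mean. Kept separate from the likelihood so it can be validated on
# closed-form toy models.
dic_core <- function(deviance_draws, deviance_at_mean) {
  bad <- !is.finite(deviance_draws)
  n_bad <- sum(bad)
  if (n_bad > 0) {
    warning(sprintf("%d non-finite deviance draws excluded.", n_bad),
            call. = FALSE)
    deviance_draws <- deviance_draws[!bad]
  }
  d_bar <- mean(deviance_draws)
  p_d <- d_bar - deviance_at_mean
  list(dic = d_bar + p_d, p_d = p_d, mean_deviance = d_bar,
       n_excluded = n_bad)
}

#' Deviance information criterion of a fitted model
#'
#' Computes the deviance `D(theta) = -2 log L(theta)` for every retained
#' draw, the posterior mean deviance `D-bar`, the effective number of
#' parameters `pD = D-bar - D(theta-bar)` (with `theta-bar` the
#' per-parameter posterior mean on the sampling scale), and
#' `DIC = D-bar + pD`. Lower DIC indicates better fit after accounting for
#' effective complexity.
#'
#' @param fit A [sample_posterior()] result.
#' @param n_draws Optional subsample size of retained draws used for the
#'   posterior-mean deviance average (all draws by default).
#' @param seed Seed for the subsample when `n_draws` is given.
#' @return An object of class `ddm_dic`: list with `dic`, `p_d`,
#'   `mean_deviance`, `n_excluded`.
#' @export
dic <- function(fit, n_draws = NULL, seed = 1) {
  stopifnot(inherits(fit, "ddm_fit"))
  model <- fit$model
  all_draws <- do.call(rbind, fit$draws)
  if (!is.null(n_draws) && n_draws < nrow(all_draws)) {
    idx <- withr::with_seed(seed,
                            sample.int(nrow(all_draws), n_draws))
    sub <- all_draws[idx, , drop = FALSE]
  } else {
    sub <- all_draws
  }
  total_ll <- function(theta) {
    sum(vapply(names(model$subject_data),
               function(sid) subject_loglik(model, theta, sid),
               numeric(1)))
  }
  dev <- -2 * apply(sub, 1, total_ll)
  theta_bar <- colMeans(all_draws)
  dev_at_mean <- -2 * total_ll(theta_bar)
  res <- dic_core(dev, dev_at_mean)
  structure(res, class = "ddm_dic")
}

#' @export
print.ddm_dic <- function(x, ...) {
  cat(sprintf("DIC = %.2f  (mean deviance %.2f, pD %.2f)\n", x$dic,
              x$mean_deviance, x$p_d))
  invisible(x)
}

#' Posterior predictive check
#'
#' Simulates a full replicate dataset on the observed design (same
#' subjects, trial counts, conditions, covariate values) for each of
#' `n_draws` parameter vectors drawn from the posterior, and summarizes
#' accuracy and reaction-time quantiles (10/30/50/70/90%) per group and
#' condition. Each observed statistic is located within its simulated
#' distribution by percentile rank. Simulated responses slower than the
#' response window are censored, mirroring the observed data.
#'
#' @param fit A [sample_posterior()] result.
#' @param n_draws Number of posterior draws to simulate from (must not
#'   exceed the retained draws).
#' @param seed Integer seed.
#' @param dt Euler-Maruyama step used for the replicate simulations; the
#'   default trades a little resolution for speed relative to the reference
#'   1e-4 step.
#' @return An object of class `ddm_ppc`: list with `summary` (tibble:
#'   `group`, `condition`, `statistic`, `observed`, `sim_mean`, `sim_q025`,
#'   `sim_q975`, `percentile`) and `n_draws`.
#' @export
posterior_predictive <- function(fit, n_draws = 500, seed = 1, dt = 1e-3) {
  stopifnot(inherits(fit, "ddm_fit"))
  model <- fit$model
  spec <- model$spec
  all_draws <- do.call(rbind, fit$draws)
  if (n_draws > nrow(all_draws)) {
    stop("`n_draws` exceeds the retained draws.", call. = FALSE)
  }
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  stat_names <- c("accuracy", sprintf("rt_q%02.0f", 100 * qs))
  summarize_trials <- function(df) {
    df |>
      dplyr::group_by(.data$group, .data$condition) |>
      dplyr::summarise(
        accuracy = mean(.data$choice),
        rt_q = list(quantile(.data$rt, qs, names = FALSE)),
        .groups = "drop"
      ) |>
      tidyr::unnest_wider("rt_q", names_sep = "_") |>
      stats::setNames(c("group", "condition", stat_names)) |>
      tidyr::pivot_longer(dplyr::all_of(stat_names),
                          names_to = "statistic", values_to = "value")
  }
  obs <- purrr::imap_dfr(model$subject_data, function(sdat, sid) {
    tibble::tibble(group = sdat$group,
                   condition = model$conditions[sdat$cond0 + 1],
                   choice = sdat$choice, rt = sdat$rt)
  })
  obs_sum <- summarize_trials(obs)
  sims <- withr::with_seed(seed, {
    idx <- sample.int(nrow(all_draws), n_draws)
    purrr::map_dfr(seq_along(idx), function(d) {
      theta <- all_draws[idx[d], ]
      rep_df <- purrr::imap_dfr(model$subject_data, function(sdat, sid) {
        eff <- group_effect_vectors(model, theta, sdat$group)
        vtr <- theta[sdat$iv] + eff$bv[sdat$cond0 + 1]
        if (ncol(sdat$X) > 0) vtr <- vtr + drop(sdat$X %*% eff$bcov)
        atr <- pmax(theta[sdat$ia] + eff$ba[sdat$cond0 + 1], 0.05)
        sim <- sim_trials_core(
          v = vtr, a = atr, z_rel = spec$z_rel, t0 = theta[sdat$it0],
          p_outlier = spec$p_outlier, rt_max = spec$rt_max,
          n = length(vtr), seed = NULL, dt = dt
        )
        keep <- sim$rt <= spec$rt_max
        tibble::tibble(group = sdat$group,
                       condition = model$conditions[sdat$cond0 + 1][keep],
                       choice = sim$choice[keep], rt = sim$rt[keep])
      })
      summarize_trials(rep_df) |> dplyr::mutate(draw = d)
    })
  })
  summary <- sims |>
    dplyr::group_by(.data$group, .data$condition, .data$statistic) |>
    dplyr::summarise(
      sim_mean = mean(.data$value),
      sim_q025 = quantile(.data$value, 0.025, names = FALSE),
      sim_q975 = quantile(.data$value, 0.975, names = FALSE),
      sim_values = list(.data$value),
      .groups = "drop"
    ) |>
    dplyr::left_join(obs_sum, by = c("group", "condition", "statistic")) |>
    dplyr::mutate(
      observed = .data$value,
      percentile = purrr::map2_dbl(.data$sim_values, .data$observed,
                                   ~ 100 * mean(.x <= .y))
    ) |>
    dplyr::select("group", "condition", "statistic", "observed",
                  "sim_mean", "sim_q025", "sim_q975", "percentile")
  structure(list(summary = summary, n_draws = n_draws, seed = seed),
            class = "ddm_ppc")
}

#' @export
print.ddm_ppc <- function(x, ...) {
  inside <- with(x$summary, mean(observed >= sim_q025 &
                                   observed <= sim_q975))
  cat("<ddm_ppc> ", x$n_draws, "posterior draws;",
      sprintf("%.0f%%", 100 * inside),
      "of observed statistics inside central 95% simulated intervals\n")
  invisible(x)
}

#' Posterior overlap between two draw sets
#'
#' Quantifies how far two posterior distributions separate. The default
#' (`method = "tail"`) forms the paired difference of seeded, equal-length
#' resampled draw streams and reports
#' `P = 100 * min(Pr(A - B > 0), Pr(A - B < 0))`: identical posteriors give
#' P near 50, disjoint posteriors give P near 0, and `P < 5` is flagged as
#' a credible difference. `method = "density"` instead reports the
#' overlapping coefficient (integral of the pointwise minimum of the two
#' kernel density estimates) as a percentage.
#'
#' @param draws_a,draws_b Numeric draw vectors (non-empty).
#' @param method `"tail"` (paired-difference tail mass, default) or
#'   `"density"` (density overlapping coefficient).
#' @param seed Seed for the pairing resample.
#' @return A one-row tibble: `P` (percent), `significant` (`P < 5`),
#'   `method`.
#' @export
posterior_overlap <- function(draws_a, draws_b,
                              method = c("tail", "density"), seed = 1) {
  method <- match.arg(method)
  stopifnot(length(draws_a) > 0, length(draws_b) > 0)
  if (method == "tail") {
    n <- max(length(draws_a), length(draws_b))
    if (length(draws_a) == length(draws_b)) {
      d <- draws_a - draws_b  # direct pairing: exactly symmetric
    } else {
      d <- withr::with_seed(seed, {
        a <- if (length(draws_a) < n) sample(draws_a, n, TRUE) else draws_a
        b <- if (length(draws_b) < n) sample(draws_b, n, TRUE) else draws_b
        a - b
      })
    }
    p <- 100 * min(mean(d > 0), mean(d < 0))
  } else {
    rng <- range(c(draws_a, draws_b))
    grid <- seq(rng[1] - 0.5 * diff(rng), rng[2] + 0.5 * diff(rng),
                length.out = 1024)
    fa <- density(draws_a, from = grid[1], to = grid[1024], n = 1024)$y
    fb <- density(draws_b, from = grid[1], to = grid[1024], n = 1024)$y
    p <- 100 * sum(pmin(fa, fb)) * (grid[2] - grid[1])
  }
  tibble::tibble(P = p, significant = p < 5, method = method)
}

#' Percentage of a posterior on one side of zero
#'
#' Reports `P = 100 * max(Pr(draw > 0), Pr(draw < 0))` together with the
#' dominant sign; `P > 95` is flagged as a credible non-zero effect.
#'
#' @param draws Numeric draw vector (non-empty).
#' @return A one-row tibble: `P` (percent), `direction` (`"positive"` or
#'   `"negative"`), `significant` (`P > 95`).
#' @export
prob_nonzero <- function(draws) {
  stopifnot(length(draws) > 0)
  p_pos <- mean(draws > 0)
  p_neg <- mean(draws < 0)
  p <- 100 * max(p_pos, p_neg)
  tibble::tibble(
    P = p,
    direction = if (p_pos >= p_neg) "positive" else "negative",
    significant = p > 95
  )
}
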