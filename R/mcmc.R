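# Exact conjugate draw of a group-mean location given the subject-level
# values x ~ N(mu, sigma^2) and a (possibly truncated) normal prior on mu.
gibbs_mu_draw <- function(x, sigma, prior) {
  prec <- 1 / prior$sd^2 + length(x) / sigma^2
  m <- (prior$mean / prior$sd^2 + sum(x) / sigma^2) / prec
  lo <- if (is.null(prior$lower)) -Inf else prior$lower
  hi <- if (is.null(prior$upper)) Inf else prior$upper
  rtruncnorm1(m, sqrt(1 / prec), lo, hi)
}

#' MCMC sampling configuration
#'
#' Desk-scale defaults (5 000 samples per chain, the first 2 000 discarded
#' as burn-in, no thinning, 2 chains) keep a full three-group cohort fit in
#' the minutes range. [study_mcmc_config()] provides the long single-study
#' preset (95 000 samples, 35 000 burn-in, thinning factor 5).
#'
#' @param n_samples Total MCMC iterations per chain (including burn-in).
#' @param n_burn_in Iterations discarded as burn-in (adaptation happens
#'   here and is frozen afterwards).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of chains (>= 2, required for convergence
#'   diagnostics).
#' @param seed Integer master seed; chain `c` uses `seed + c`.
#' @param target_accept Target acceptance rate for the adaptive proposals.
#' @param init_dispersion Scale of the overdispersed initial jitter.
#' @param adapt_interval Iterations per adaptation batch during burn-in.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 5000, n_burn_in = 2000, thin = 1,
                        n_chains = 2, seed = 1, target_accept = 0.35,
                        init_dispersion = 1, adapt_interval = 25) {
  if (!(n_samples > n_burn_in && n_burn_in >= 0)) {
    stop("Need n_samples > n_burn_in >= 0.", call. = FALSE)
  }
  if (thin < 1) stop("`thin` must be >= 1.", call. = FALSE)
  if (n_chains < 2) stop("`n_chains` must be >= 2.", call. = FALSE)
  structure(
    list(n_samples = as.integer(n_samples),
         n_burn_in = as.integer(n_burn_in), thin = as.integer(thin),
         n_chains = as.integer(n_chains), seed = as.integer(seed),
         target_accept = target_accept, init_dispersion = init_dispersion,
         adapt_interval = as.integer(adapt_interval)),
    class = "mcmc_config"
  )
}

#' @rdname mcmc_config
#' @export
study_mcmc_config <- function(seed = 1) {
  mcmc_config(n_samples = 95000, n_burn_in = 35000, thin = 5,
              n_chains = 2, seed = seed)
}

#' Sample the joint posterior by adaptive Metropolis-within-Gibbs
#'
#' Runs `n_chains` independent chains from overdispersed, data-informed
#' initializations. Group-mean locations are updated by exact conjugate
#' (truncated-)normal Gibbs steps given the subject-level values;
#' between-subject SDs, condition effects, covariate coefficients and
#' subject-level parameters are updated by random-walk Metropolis steps
#' whose scales adapt toward the target acceptance rate during burn-in and
#' are frozen afterwards, so retained draws come from a fixed kernel.
#' Identical `(model, config)` give identical draws.
#'
#' @param model A [build_model()] result.
#' @param config An [mcmc_config()].
#' @param progress Print per-chain progress.
#' @return An object of class `ddm_fit` containing the retained draws
#'   (per-chain matrices), the model, config, and acceptance rates.
#' @export
sample_posterior <- function(model, config = mcmc_config(),
                             progress = FALSE) {
  stopifnot(inherits(model, "ddm_model"), inherits(config, "mcmc_config"))
  t_start <- Sys.time()
  draws <- vector("list", config$n_chains)
  accepts <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    draws_ch <- withr::with_seed(config$seed + ch, {
      run_chain(model, config, chain = ch, progress = progress)
    })
    draws[[ch]] <- draws_ch$draws
    accepts[[ch]] <- draws_ch$accept
  }
  structure(
    list(model = model, config = config, draws = draws,
         accept = accepts,
         runtime_s = as.numeric(difftime(Sys.time(), t_start,
                                         units = "secs"))),
    class = "ddm_fit"
  )
}

# One MCMC chain. Assumes the RNG state has been seeded by the caller.
run_chain <- function(model, config, chain, progress = FALSE) {
  spec <- model$spec
  params <- model$params
  P <- nrow(params)
  lower <- params$lower
  upper <- params$upper
  roles <- params$role
  pr <- spec$priors

  sids <- names(model$subject_data)
  S <- length(sids)
  sdix <- setNames(seq_len(S), sids)

  # --- initialization (data-informed + overdispersed jitter) -------------
  disp <- config$init_dispersion
  init_theta <- function() {
    theta <- numeric(P)
    sub_init <- list()
    for (sid in sids) {
      sdat <- model$subject_data[[sid]]
      acc <- mean(sdat$choice)
      v0 <- stats::qlogis(min(max(acc, 0.55), 0.98)) * 0.8 +
        rnorm(1, 0, 0.4 * disp)
      a0 <- 1.5 + rnorm(1, 0, 0.3 * disp)
      t00 <- min(max(0.5 * min(sdat$rt), 0.06), 0.8) +
        rnorm(1, 0, 0.05 * disp)
      theta[sdat$iv] <- min(max(v0, -5), 8)
      theta[sdat$ia] <- min(max(a0, 0.3), 4)
      theta[sdat$it0] <- min(max(t00, 0.02), 1.2)
      sub_init[[sid]] <- c(theta[sdat$iv], theta[sdat$ia], theta[sdat$it0])
    }
    for (g in model$groups) {
      gi <- model$group_index[[g]]
      vals <- do.call(rbind, sub_init[gi$subjects])
      theta[gi$mu_v] <- mean(vals[, 1]) + rnorm(1, 0, 0.2 * disp)
      theta[gi$mu_a] <- min(max(mean(vals[, 2]) + rnorm(1, 0, 0.15 * disp),
                                pr$mu_a$lower), pr$mu_a$upper)
      theta[gi$mu_t0] <- min(max(mean(vals[, 3]) + rnorm(1, 0, 0.05 * disp),
                                 pr$mu_t0$lower), pr$mu_t0$upper)
      theta[gi$sigma_v] <- runif(1, 0.15, 0.6)
      theta[gi$sigma_a] <- runif(1, 0.1, 0.5)
      theta[gi$sigma_t0] <- runif(1, 0.03, 0.15)
      for (i in c(gi$bv, gi$ba)) theta[i] <- rnorm(1, 0, 0.15 * disp)
      for (i in gi$bcov) theta[i] <- rnorm(1, 0, 0.1 * disp)
    }
    theta
  }

  eval_subj <- function(theta, eff_g, sid) {
    sdat <- model$subject_data[[sid]]
    eff <- eff_g[[sdat$group]]
    ddm_subject_loglik_cpp(
      sdat$rt, sdat$choice, sdat$cond0,
      theta[sdat$iv], theta[sdat$ia], theta[sdat$it0],
      eff$bv, eff$ba, sdat$X, eff$bcov,
      spec$z_rel, spec$p_outlier, spec$rt_max, spec$eps
    )
  }
  make_eff <- function(theta) {
    setNames(lapply(model$groups,
                    function(g) group_effect_vectors(model, theta, g)),
             model$groups)
  }

  theta <- NULL
  subj_ll <- NULL
  for (try in 1:25) {
    theta <- init_theta()
    eff_g <- make_eff(theta)
    subj_ll <- vapply(sids, function(sid) eval_subj(theta, eff_g, sid),
                      numeric(1))
    if (all(is.finite(subj_ll))) break
    if (try == 25) {
      stop("Could not find a finite-likelihood initialization.",
           call. = FALSE)
    }
  }
  eff_g <- make_eff(theta)

  # --- proposal scales ---------------------------------------------------
  prop_sd <- numeric(P)
  prop_sd[roles == "subject" & params$param == "v"] <- 0.3
  prop_sd[roles == "subject" & params$param == "a"] <- 0.15
  prop_sd[roles == "subject" & params$param == "t0"] <- 0.04
  prop_sd[roles == "cond_effect"] <- 0.12
  prop_sd[roles == "cov_coef"] <- 0.08
  prop_sd[roles == "hyper_sigma"] <- 0.4  # on the log scale
  n_prop <- numeric(P)
  n_acc <- numeric(P)
  batch_prop <- numeric(P)
  batch_acc <- numeric(P)

  prior_effect <- function(x) dnorm(x, pr$cond_effect$mean,
                                    pr$cond_effect$sd, log = TRUE)
  prior_cov <- function(x) dnorm(x, pr$cov_coef$mean, pr$cov_coef$sd,
                                 log = TRUE)

  n_keep <- (config$n_samples - config$n_burn_in) %/% config$thin
  out <- matrix(NA_real_, nrow = n_keep, ncol = P,
                dimnames = list(NULL, params$name))
  keep_row <- 0L

  mu_prior <- list(v = pr$mu_v, a = pr$mu_a, t0 = pr$mu_t0)

  for (iter in seq_len(config$n_samples)) {
    adapting <- iter <= config$n_burn_in
    # 1. conjugate Gibbs for group means -----------------------------------
    for (g in model$groups) {
      gi <- model$group_index[[g]]
      subs <- gi$subjects
      for (p in c("v", "a", "t0")) {
        imu <- gi[[paste0("mu_", p)]]
        isig <- gi[[paste0("sigma_", p)]]
        xpos <- vapply(subs, function(sid) {
          model$subject_data[[sid]][[switch(p, v = "iv", a = "ia",
                                            t0 = "it0")]]
        }, integer(1))
        x <- theta[xpos]
        theta[imu] <- gibbs_mu_draw(x, theta[isig], mu_prior[[p]])
        # 2. MH on log(sigma); two passes per sweep (cheap: no trial
        # likelihood involved) to improve scale mixing
        for (pass in 1:2) {
          cur <- theta[isig]
          ls <- log(cur)
          lsp <- ls + rnorm(1, 0, prop_sd[isig])
          propv <- exp(lsp)
          batch_prop[isig] <- batch_prop[isig] + 1
          n_prop[isig] <- n_prop[isig] + 1
          if (propv >= lower[isig] && propv <= upper[isig]) {
            mu <- theta[imu]
            ll_new <- sum(dnorm(x, mu, propv, log = TRUE))
            ll_cur <- sum(dnorm(x, mu, cur, log = TRUE))
            la <- (ll_new + dnorm(propv, 0, pr$sigma$scale, log = TRUE) +
                     lsp) -
              (ll_cur + dnorm(cur, 0, pr$sigma$scale, log = TRUE) + ls)
            if (log(runif(1)) < la) {
              theta[isig] <- propv
              batch_acc[isig] <- batch_acc[isig] + 1
              n_acc[isig] <- n_acc[isig] + 1
            }
          }
        }
      }
      # 3. condition effects and covariate coefficients --------------------
      coef_pos <- c(gi$bv, gi$ba, gi$bcov)
      if (length(coef_pos) > 0) {
        sub_idx <- sdix[subs]
        for (i in coef_pos) {
          cur <- theta[i]
          propv <- cur + rnorm(1, 0, prop_sd[i])
          batch_prop[i] <- batch_prop[i] + 1
          n_prop[i] <- n_prop[i] + 1
          theta[i] <- propv
          eff_try <- eff_g
          eff_try[[g]] <- group_effect_vectors(model, theta, g)
          new_lls <- vapply(subs,
                            function(sid) {
                              sdat <- model$subject_data[[sid]]
                              eff <- eff_try[[g]]
                              ddm_subject_loglik_cpp(
                                sdat$rt, sdat$choice, sdat$cond0,
                                theta[sdat$iv], theta[sdat$ia],
                                theta[sdat$it0], eff$bv, eff$ba, sdat$X,
                                eff$bcov, spec$z_rel, spec$p_outlier,
                                spec$rt_max, spec$eps)
                            }, numeric(1))
          lp <- if (roles[i] == "cov_coef") prior_cov else prior_effect
          la <- sum(new_lls) - sum(subj_ll[sub_idx]) + lp(propv) - lp(cur)
          if (is.finite(la) && log(runif(1)) < la) {
            subj_ll[sub_idx] <- new_lls
            eff_g <- eff_try
            batch_acc[i] <- batch_acc[i] + 1
            n_acc[i] <- n_acc[i] + 1
          } else {
            theta[i] <- cur
          }
        }
      }
    }
    # 4. subject-level parameters ------------------------------------------
    for (si in seq_len(S)) {
      sid <- sids[si]
      sdat <- model$subject_data[[sid]]
      gi <- model$group_index[[sdat$group]]
      eff <- eff_g[[sdat$group]]
      for (p in c("v", "a", "t0")) {
        i <- sdat[[switch(p, v = "iv", a = "ia", t0 = "it0")]]
        imu <- gi[[paste0("mu_", p)]]
        isig <- gi[[paste0("sigma_", p)]]
        cur <- theta[i]
        propv <- cur + rnorm(1, 0, prop_sd[i])
        batch_prop[i] <- batch_prop[i] + 1
        n_prop[i] <- n_prop[i] + 1
        if (propv < lower[i] || propv > upper[i]) next
        theta[i] <- propv
        new_ll <- ddm_subject_loglik_cpp(
          sdat$rt, sdat$choice, sdat$cond0,
          theta[sdat$iv], theta[sdat$ia], theta[sdat$it0],
          eff$bv, eff$ba, sdat$X, eff$bcov,
          spec$z_rel, spec$p_outlier, spec$rt_max, spec$eps
        )
        la <- (new_ll + dnorm(propv, theta[imu], theta[isig], log = TRUE)) -
          (subj_ll[si] + dnorm(cur, theta[imu], theta[isig], log = TRUE))
        if (is.finite(la) && log(runif(1)) < la) {
          subj_ll[si] <- new_ll
          batch_acc[i] <- batch_acc[i] + 1
          n_acc[i] <- n_acc[i] + 1
        } else {
          theta[i] <- cur
        }
      }
    }
    # adaptation (burn-in only, frozen afterwards) -------------------------
    if (adapting && iter %% config$adapt_interval == 0) {
      active <- batch_prop > 0
      rate <- ifelse(active, batch_acc / pmax(batch_prop, 1), NA)
      step <- min(0.3, 3 / sqrt(iter))
      up <- active & !is.na(rate) & rate > config$target_accept + 0.10
      dn <- active & !is.na(rate) & rate < config$target_accept - 0.10
      prop_sd[up] <- prop_sd[up] * exp(step)
      prop_sd[dn] <- prop_sd[dn] * exp(-step)
      batch_prop[] <- 0
      batch_acc[] <- 0
    }
    if (!adapting) {
      k <- iter - config$n_burn_in
      if (k %% config$thin == 0L) {
        keep_row <- keep_row + 1L
        out[keep_row, ] <- theta
      }
    }
    if (progress && iter %% 500 == 0) {
      message(sprintf("chain %d: iter %d / %d", chain, iter,
                      config$n_samples))
    }
  }
  list(draws = out[seq_len(keep_row), , drop = FALSE],
       accept = setNames(ifelse(n_prop > 0, n_acc / pmax(n_prop, 1),
                                NA_real_), params$name))
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("<ddm_fit> ", length(x$draws), "chains x", nrow(x$draws[[1]]),
      "retained draws |", ncol(x$draws[[1]]), "parameters |",
      sprintf("%.1f s\n", x$runtime_s))
  invisible(x)
}

#' Long tibble of posterior draws
#'
#' @param fit A [sample_posterior()] result.
#' @param pars Optional character vector of parameter names to keep.
#' @return A tibble with columns `chain`, `.iteration`, `parameter`,
#'   `value`.
#' @export
posterior_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  purrr::imap_dfr(fit$draws, function(m, ch) {
    if (!is.null(pars)) m <- m[, intersect(pars, colnames(m)), drop = FALSE]
    tibble::as_tibble(m) |>
      dplyr::mutate(chain = ch, .iteration = dplyr::row_number()) |>
      tidyr::pivot_longer(cols = -c("chain", ".iteration"),
                          names_to = "parameter", values_to = "value")
  })
}

#' @export
tidy.ddm_fit <- function(x, conf_level = 0.95, ...) {
  al <- (1 - conf_level) / 2
  all_draws <- do.call(rbind, x$draws)
  rh <- gelman_rubin(x)
  tibble::tibble(
    term = colnames(all_draws),
    estimate = colMeans(all_draws),
    std.error = apply(all_draws, 2, sd),
    conf.low = apply(all_draws, 2, quantile, probs = al),
    conf.high = apply(all_draws, 2, quantile, probs = 1 - al)
  ) |>
    dplyr::left_join(rh, by = c(term = "parameter"))
}

#' @export
glance.ddm_fit <- function(x, ...) {
  rh <- gelman_rubin(x)
  tibble::tibble(
    n_chains = length(x$draws),
    n_draws = nrow(x$draws[[1]]),
    n_parameters = ncol(x$draws[[1]]),
    n_subjects = nrow(x$model$subjects),
    n_trials = x$model$n_trials,
    max_rhat = max(rh$rhat, na.rm = TRUE),
    runtime_s = x$runtime_s
  )
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' Splits each chain in half and computes the potential scale reduction
#' factor per parameter; values below 1.1 are taken as successful
#' convergence. Parameters with zero within-chain variance are reported as
#' degenerate rather than producing a division by zero.
#'
#' @param fit A `ddm_fit`, or a list of draws matrices (iterations x
#'   parameters, equal sizes) one per chain.
#' @return A tibble with columns `parameter`, `rhat`, `flagged`
#'   (`rhat >= 1.1`), `degenerate`.
#' @export
gelman_rubin <- function(fit) {
  mats <- if (inherits(fit, "ddm_fit")) fit$draws else fit
  stopifnot(is.list(mats), length(mats) >= 2)
  n <- nrow(mats[[1]])
  if (n < 10) stop("Need >= 10 retained draws per chain.", call. = FALSE)
  half <- n %/% 2
  split_mats <- purrr::flatten(purrr::map(mats, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1):n, , drop = FALSE])
  }))
  pnames <- colnames(mats[[1]])
  rhat <- vapply(seq_along(pnames), function(j) {
    ch <- vapply(split_mats, function(m) m[, j], numeric(half))
    w <- mean(apply(ch, 2, var))
    b <- half * var(colMeans(ch))
    if (w == 0) return(NA_real_)
    sqrt((half - 1) / half + b / (w * half))
  }, numeric(1))
  tibble::tibble(
    parameter = pnames, rhat = rhat,
    flagged = !is.na(rhat) & rhat >= 1.1,
    degenerate = is.na(rhat)
  )
}

#' Reconstruct per-condition group-level posteriors
#'
#' Combines, draw by draw, each group's baseline posterior with its
#' condition-effect posteriors under the treatment coding: the congruent
#' condition equals the baseline draws exactly and the incongruent
#' conditions add their effect draws. Non-decision time (condition-invariant
#' by construction) is returned with condition `"all"`.
#'
#' @param fit A [sample_posterior()] result.
#' @return A tibble with columns `chain`, `.iteration`, `group`,
#'   `parameter` (`"v"`, `"a"`, `"t0"`), `condition`, `value`.
#' @export
reconstruct_condition_posteriors <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  model <- fit$model
  conds <- model$conditions
  out <- list()
  for (ch in seq_along(fit$draws)) {
    m <- fit$draws[[ch]]
    iters <- seq_len(nrow(m))
    for (g in model$groups) {
      gi <- model$group_index[[g]]
      for (p in c("v", "a")) {
        base <- m[, model$params$name[gi[[paste0("mu_", p)]]]]
        eff_pos <- if (p == "v") gi$bv else gi$ba
        for (ci in seq_along(conds)) {
          val <- base
          if (ci > 1 && length(eff_pos) > 0) {
            val <- base + m[, model$params$name[eff_pos[ci - 1]]]
          }
          out[[length(out) + 1]] <- tibble::tibble(
            chain = ch, .iteration = iters, group = g, parameter = p,
            condition = conds[ci], value = unname(val)
          )
        }
      }
      out[[length(out) + 1]] <- tibble::tibble(
        chain = ch, .iteration = iters, group = g, parameter = "t0",
        condition = "all",
        value = unname(m[, model$params$name[gi$mu_t0]])
      )
    }
  }
  dplyr::bind_rows(out)
}
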