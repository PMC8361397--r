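#' Log density of the Wiener first-passage time
#'
#' Evaluates the log of the defective first-passage density of the diffusion
#' process at the indicated boundary, as a function of the observed response
#' time (decision time plus non-decision time), mixed with the uniform
#' contaminant component when `p_outlier > 0`. The density is computed from
#' the small-time and large-time series expansions of the Wiener
#' first-passage distribution, switching to whichever needs fewer terms for a
#' truncation error below `eps`.
#'
#' @param rt Vector of observed response times in seconds (> 0).
#' @param choice Vector of boundary indicators: 1 = upper (correct under
#'   accuracy coding), 0 = lower (error). Recycled against `rt`.
#' @param params A [ddm_params()] object.
#' @param eps Truncation tolerance for the series expansion (on the
#'   normalized-time density).
#'
#' @return Numeric vector of log densities; `-Inf` where the density is zero
#'   (e.g. `rt <= t0` with no contaminant mass).
#' @examples
#' p <- ddm_params(v = 1, a = 2, t0 = 0.3)
#' wfpt_log_density(c(0.6, 1.0), c(1, 0), p)
#' @export
wfpt_log_density <- function(rt, choice, params, eps = 1e-6) {
  assert_ddm_params(params)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    stop("`eps` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(rt) || any(!is.finite(rt)) || any(rt <= 0)) {
    stop("`rt` must be finite and > 0.", call. = FALSE)
  }
  choice <- as.integer(choice)
  if (any(!choice %in% c(0L, 1L))) {
    stop("`choice` must be 0 (lower) or 1 (upper).", call. = FALSE)
  }
  n <- max(length(rt), length(choice))
  rt <- rep_len(rt, n)
  choice <- rep_len(choice, n)
  wfpt_logdens_cpp(rt, choice, params$v, params$a, params$z_rel, params$t0,
                   params$p_outlier, params$rt_max, eps)
}

#' Closed-form probability of upper-boundary absorption
#'
#' For a diffusion with drift `v`, boundary separation `a`, relative start
#' `w` and unit diffusion scale, the probability of absorption at the upper
#' boundary is `(1 - exp(-2 v a w)) / (1 - exp(-2 v a))`, with limit `w` as
#' `v -> 0`. Only defined for the pure decision process (`p_outlier = 0`).
#'
#' @param params A [ddm_params()] object with `p_outlier = 0`.
#' @return Probability of absorption at the upper (correct) boundary.
#' @examples
#' choice_probability(ddm_params(v = 1, a = 2))  # 1 / (1 + exp(-2))
#' @export
choice_probability <- function(params) {
  assert_ddm_params(params)
  if (params$p_outlier > 0) {
    stop("choice_probability() is defined for p_outlier = 0 only.",
         call. = FALSE)
  }
  upper_prob(params$v, params$a, params$z_rel)
}

upper_prob <- function(v, a, w) {
  va <- v * a
  if (abs(va) < 1e-10) return(w)
  # (1 - e^{-2 v a w}) / (1 - e^{-2 v a}) via expm1 for numerical stability
  expm1(-2 * va * w) / expm1(-2 * va)
}

#' Closed-form expected decision time
#'
#' Mean first-passage time of the diffusion (excluding non-decision time),
#' unconditional on the absorbing boundary:
#' `E[T] = (a / v) * P(upper) - z / v` with `z = z_rel * a`, and the limit
#' `z * (a - z)` as `v -> 0`. For `z_rel = 0.5` this reduces to
#' `(a / (2 v)) * tanh(v a / 2)`.
#'
#' @inheritParams choice_probability
#' @return Expected decision time in seconds.
#' @examples
#' mean_decision_time(ddm_params(v = 1, a = 2))  # tanh(1)
#' @export
mean_decision_time <- function(params) {
  assert_ddm_params(params)
  if (params$p_outlier > 0) {
    stop("mean_decision_time() is defined for p_outlier = 0 only.",
         call. = FALSE)
  }
  v <- params$v; a <- params$a; w <- params$z_rel
  z <- w * a
  if (abs(v * a) < 1e-4) return(z * (a - z))
  (a * upper_prob(v, a, w) - z) / v
}

#' Simulate diffusion-model trials
#'
#' Draws independent (choice, rt) pairs from the drift-diffusion process by
#' Euler-Maruyama integration of the evidence path (step `dt`), with the
#' contaminant mixture applied: each trial is a contaminant with probability
#' `p_outlier`, in which case the response time is uniform on
#' `(0, rt_max)` and the choice a fair coin.
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials.
#' @param seed Integer seed; identical seeds give identical output. `NULL`
#'   continues the current RNG stream.
#' @param dt Euler-Maruyama step size in seconds.
#' @param max_decision_time Hard cap on the simulated decision time; paths
#'   still unabsorbed are assigned the nearer boundary. Under task-realistic
#'   parameters these are censored by the response window downstream.
#'
#' @return A tibble with columns `trial`, `choice` (1 = upper/correct),
#'   `rt` (seconds), and `outlier` (ground-truth contaminant flag).
#' @examples
#' simulate_trials(ddm_params(v = 1.5, a = 1.5, t0 = 0.3), n = 5, seed = 1)
#' @export
simulate_trials <- function(params, n, seed = NULL, dt = 1e-4,
                            max_decision_time = 20) {
  assert_ddm_params(params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  sim_trials_core(
    v = params$v, a = params$a, z_rel = params$z_rel, t0 = params$t0,
    p_outlier = params$p_outlier, rt_max = params$rt_max, n = as.integer(n),
    seed = seed, dt = dt, max_decision_time = max_decision_time
  )
}

# Shared simulation path: `v` and `a` may be per-trial vectors. The RNG
# consumption order (outlier flags, then diffusion paths, then contaminant
# draws) is fixed so that a zero covariate coupling reproduces the uncoupled
# stream exactly.
sim_trials_core <- function(v, a, z_rel, t0, p_outlier, rt_max, n,
                            seed = NULL, dt = 1e-4, max_decision_time = 20) {
  v <- rep_len(v, n)
  a <- rep_len(a, n)
  run <- function() {
    out_flag <- runif(n) < p_outlier
    sim <- sim_ddm_em_cpp(v, a, z_rel, dt, max_decision_time)
    choice <- sim$boundary
    rt <- t0 + sim$decision_time
    n_out <- sum(out_flag)
    if (n_out > 0) {
      rt[out_flag] <- runif(n_out, 0, rt_max)
      choice[out_flag] <- rbinom(n_out, 1L, 0.5)
    }
    tibble::tibble(trial = seq_len(n), choice = as.integer(choice), rt = rt,
                   outlier = out_flag)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
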