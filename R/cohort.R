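#' Group-level generating parameters for a synthetic cohort
#'
#' Describes one clinical group's generating distribution: per-condition
#' group-mean drift rates and boundaries, a group-mean non-decision time,
#' between-subject standard deviations, and the linear couplings of
#' trial-wise network activity (z-scored beta series) onto drift rate.
#' Condition effects are shared across subjects within a group; subjects
#' vary in their baselines (normal for drift, positively truncated normal
#' for boundary and non-decision time).
#'
#' @param label Group label (e.g. "Control").
#' @param v Group-mean drift rates: length 3 (congruent, incongruent-EASY,
#'   incongruent-HARD) or length 1 (condition-invariant).
#' @param a Group-mean boundary separations, length 3 or 1; all > 0.
#' @param t0 Group-mean non-decision time in seconds.
#' @param sd_v,sd_a,sd_t0 Between-subject standard deviations (>= 0).
#' @param b_default,b_dorsal Drift-rate change per 1 SD of default-network /
#'   dorsal-attention-network trial-wise activity.
#'
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(label, v, a, t0, sd_v = 0.3, sd_a = 0.2,
                       sd_t0 = 0.05, b_default = 0, b_dorsal = 0) {
  v <- rep_len(as.numeric(v), 3L)
  a <- rep_len(as.numeric(a), 3L)
  if (any(a <= 0)) stop("Boundaries must be positive.", call. = FALSE)
  if (any(c(sd_v, sd_a, sd_t0) < 0)) {
    stop("Between-subject SDs must be non-negative.", call. = FALSE)
  }
  if (t0 < 0) stop("`t0` must be non-negative.", call. = FALSE)
  structure(
    list(label = label, v = setNames(v, ant_conditions),
         a = setNames(a, ant_conditions), t0 = t0,
         sd_v = sd_v, sd_a = sd_a, sd_t0 = sd_t0,
         b_default = b_default, b_dorsal = b_dorsal),
    class = "group_spec"
  )
}

#' Default three-group cohort configuration
#'
#' Generating values for a Control / Alzheimer's disease (AD) / Lewy body
#' dementia (LBD) cohort, chosen to reproduce the qualitative ordering of
#' the clinical findings: drift rates Control > AD > LBD in every condition
#' and decreasing with conflict; boundaries reduced in both patient groups
#' relative to controls but equal between patient groups; non-decision time
#' Control < AD < LBD; dorsal-attention coupling positive in all groups;
#' default-network coupling weakly positive in Control and AD, negative in
#' LBD. These are invented configuration values, not estimates from any
#' patient dataset.
#'
#' @return A named list of three [group_spec()] objects.
#' @export
default_group_specs <- function() {
  list(
    Control = group_spec("Control", v = c(2.8, 2.2, 2.0), a = 2.0,
                         t0 = 0.35, b_default = 0.1, b_dorsal = 0.3),
    AD = group_spec("AD", v = c(2.0, 1.5, 1.3), a = 1.5, t0 = 0.45,
                    b_default = 0.05, b_dorsal = 0.3),
    LBD = group_spec("LBD", v = c(1.6, 1.1, 0.9), a = 1.5, t0 = 0.55,
                     b_default = -0.2, b_dorsal = 0.3)
  )
}

#' Cohort configuration with condition-varying boundaries
#'
#' Variant of [default_group_specs()] in which the decision boundary also
#' varies across conditions (-0.25 / -0.5 relative to congruent), used for
#' model-selection studies where the generating model must contain both
#' condition-dependent drift and condition-dependent boundary.
#'
#' @return A named list of three [group_spec()] objects.
#' @export
model_selection_group_specs <- function() {
  specs <- default_group_specs()
  for (g in names(specs)) {
    base <- specs[[g]]$a[1]
    specs[[g]]$a <- setNames(base + c(0, -0.25, -0.5), ant_conditions)
  }
  specs
}

#' Generate a synthetic behavioural cohort
#'
#' Draws subject-level parameters from each group's generating distribution,
#' simulates every trial of a randomized task schedule through the
#' drift-diffusion process (with per-trial drift modulated by z-scored
#' network activity via the group couplings), applies the response-window
#' censoring rule, and returns both the observable trial table and the
#' hidden ground truth for recovery testing.
#'
#' Per-trial network activity (`beta_default`, `beta_dorsal`) is drawn
#' i.i.d. standard normal, playing the role of z-scored single-trial beta
#' series. Trials slower than the response window are emitted as censored
#' records (`missed = TRUE`, `response` and `rt` missing) so that inclusion
#' filters can be exercised. Contaminant trials (uniform response time, fair
#' choice) occur at rate `p_outlier`.
#'
#' @param groups List of [group_spec()] objects (e.g.
#'   [default_group_specs()]).
#' @param n_subjects_per_group Subjects per group (>= 1).
#' @param schedule A [schedule_config()].
#' @param seed Integer seed for full reproducibility.
#' @param p_outlier Contaminant rate used in generation.
#' @param dt Euler-Maruyama step size for trial simulation.
#'
#' @return An object of class `ddm_cohort`: a list with `trials` (tibble:
#'   `subject_id`, `group`, `run`, `trial_index`, `condition`, `response`,
#'   `rt`, `beta_default`, `beta_dorsal`, `missed`, `outlier`), `subjects`
#'   (tibble of true subject-level parameters), and `groups` (the generating
#'   specs).
#' @examples
#' coh <- generate_cohort(default_group_specs(), 2,
#'                        schedule_config(n_runs = 5), seed = 1)
#' dplyr::count(coh$trials, group)
#' @export
generate_cohort <- function(groups, n_subjects_per_group,
                            schedule = schedule_config(), seed = NULL,
                            p_outlier = 0.05, dt = 1e-4) {
  stopifnot(is.list(groups), length(groups) >= 1,
            n_subjects_per_group >= 1)
  purrr::walk(groups, function(g) {
    if (!inherits(g, "group_spec")) {
      stop("Every element of `groups` must be a group_spec().",
           call. = FALSE)
    }
  })
  build <- function() {
    all_trials <- list()
    all_subjects <- list()
    for (g in groups) {
      for (i in seq_len(n_subjects_per_group)) {
        sid <- sprintf("%s_%02d", g$label, i)
        v_s <- rnorm(1, g$v[1], g$sd_v)
        a_s <- rtruncnorm1(g$a[1], g$sd_a, lower = 0.1)
        t0_s <- rtruncnorm1(g$t0, g$sd_t0, lower = 0.05)
        sched <- generate_trial_schedule(schedule, seed = NULL)
        n_tr <- nrow(sched)
        bd <- rnorm(n_tr)
        bdor <- rnorm(n_tr)
        ci <- as.integer(sched$condition)
        v_trial <- v_s + (g$v[ci] - g$v[1]) +
          g$b_default * bd + g$b_dorsal * bdor
        a_trial <- a_s + (g$a[ci] - g$a[1])
        a_trial <- pmax(a_trial, 0.1)
        sim <- sim_trials_core(
          v = v_trial, a = a_trial, z_rel = 0.5, t0 = t0_s,
          p_outlier = p_outlier, rt_max = schedule$response_window,
          n = n_tr, seed = NULL, dt = dt
        )
        missed <- sim$rt > schedule$response_window
        all_trials[[sid]] <- tibble::tibble(
          subject_id = sid, group = g$label,
          run = sched$run, trial_index = sched$trial_index,
          condition = sched$condition,
          response = ifelse(missed, NA_integer_, sim$choice),
          rt = ifelse(missed, NA_real_, sim$rt),
          beta_default = bd, beta_dorsal = bdor,
          missed = missed, outlier = sim$outlier
        )
        all_subjects[[sid]] <- tibble::tibble(
          subject_id = sid, group = g$label, v = v_s, a = a_s, t0 = t0_s
        )
      }
    }
    structure(
      list(trials = dplyr::bind_rows(all_trials),
           subjects = dplyr::bind_rows(all_subjects),
           groups = groups, schedule = schedule,
           p_outlier = p_outlier),
      class = "ddm_cohort"
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.ddm_cohort <- function(x, ...) {
  cat("<ddm_cohort> ", nrow(x$subjects), "subjects,", nrow(x$trials),
      "trials,", length(x$groups), "groups\n")
  invisible(x)
}

#' Simulate trials with drift coupled to a trial-wise covariate
#'
#' Trial `k` is simulated with drift `v + b * betas[k]` while boundary,
#' starting point and non-decision time are unchanged; with `b = 0` and the
#' same seed, output is identical to [simulate_trials()].
#'
#' @param params A [ddm_params()] object providing the baseline parameters.
#' @param betas Per-trial covariate values; expected to be z-scored
#'   (mean approximately 0, SD approximately 1).
#' @param b Coupling in drift units per covariate SD.
#' @inheritParams simulate_trials
#' @return A tibble as from [simulate_trials()], plus a `beta` column.
#' @export
generate_coupled_trials <- function(params, betas, b, seed = NULL,
                                    dt = 1e-4) {
  assert_ddm_params(params)
  if (any(!is.finite(betas))) {
    stop("`betas` must be finite.", call. = FALSE)
  }
  if (length(betas) > 2 &&
      (abs(mean(betas)) > 0.25 || abs(sd(betas) - 1) > 0.5)) {
    warning("`betas` do not look z-scored (mean ~ 0, SD ~ 1).",
            call. = FALSE)
  }
  out <- sim_trials_core(
    v = params$v + b * betas, a = params$a, z_rel = params$z_rel,
    t0 = params$t0, p_outlier = params$p_outlier, rt_max = params$rt_max,
    n = length(betas), seed = seed, dt = dt
  )
  out$beta <- betas
  out
}

# Truncated-normal draw by inverse-CDF; exact for a single value.
rtruncnorm1 <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(1, plo, phi), mean, sd)
}
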