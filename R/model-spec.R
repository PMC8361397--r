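#' Default priors for the hierarchical model
#'
#' Weakly informative priors on the unit diffusion-scale parameterization:
#' group-mean drift Normal(2, 3^2); group-mean boundary Normal(1.5, 1^2)
#' truncated to (0.3, 4); group-mean non-decision time Normal(0.3, 0.25^2)
#' truncated to (0.05, 1); between-subject SDs Half-Normal(1); condition
#' effects Normal(0, 2^2); trial-wise covariate coefficients Normal(0, 1).
#'
#' @return A named list of prior descriptions.
#' @export
default_priors <- function() {
  list(
    mu_v = list(mean = 2, sd = 3, lower = -Inf, upper = Inf),
    mu_a = list(mean = 1.5, sd = 1, lower = 0.3, upper = 4),
    mu_t0 = list(mean = 0.3, sd = 0.25, lower = 0.05, upper = 1),
    sigma = list(scale = 1),
    cond_effect = list(mean = 0, sd = 2),
    cov_coef = list(mean = 0, sd = 1)
  )
}

#' Specify a hierarchical drift-diffusion model
#'
#' Declares which decision parameters vary by condition, which trial-wise
#' covariates enter the drift equation (with group-level-only coefficients),
#' and the fixed components: non-decision time constant across conditions,
#' unbiased starting point (`z_rel = 0.5`), and a fixed contaminant mixture
#' weight. The three study variants are `varies = "v"`, `varies = "a"`, and
#' `varies = c("v", "a")`.
#'
#' @param varies Which of `"v"`, `"a"` receive condition effects.
#' @param covariates Names of per-trial covariate columns entering drift
#'   (e.g. `c("beta_default", "beta_dorsal")`).
#' @param p_outlier Fixed contaminant mixture weight.
#' @param priors Prior table, see [default_priors()].
#' @param rt_max Contaminant support / response window in seconds.
#' @param eps Series truncation tolerance for the likelihood.
#' @return An object of class `ddm_model_spec`.
#' @export
ddm_model_spec <- function(varies = c("v", "a"), covariates = character(),
                           p_outlier = 0.05, priors = default_priors(),
                           rt_max = 3, eps = 1e-6) {
  varies <- unique(varies)
  if (length(varies) > 0 && !all(varies %in% c("v", "a"))) {
    stop("`varies` must be a subset of c(\"v\", \"a\").", call. = FALSE)
  }
  if (p_outlier < 0 || p_outlier >= 1) {
    stop("`p_outlier` must lie in [0, 1).", call. = FALSE)
  }
  structure(
    list(varies = varies, covariates = covariates, p_outlier = p_outlier,
         priors = priors, rt_max = rt_max, eps = eps, z_rel = 0.5),
    class = "ddm_model_spec"
  )
}

#' Build the hierarchical parameter graph for a trial table
#'
#' Indexes the data and lays out the model's parameter vector: per clinical
#' group, location/scale hyper-parameters for subject-level drift, boundary
#' and non-decision time; condition-effect coefficients (treatment coding
#' against the congruent baseline) for each parameter declared in the spec;
#' and one coefficient per covariate per group. Subject-level baselines are
#' shrunk toward their group's hyper-distribution.
#'
#' @param spec A [ddm_model_spec()].
#' @param data A trial tibble with columns `subject_id`, `group`,
#'   `condition`, `response` (0/1), `rt` (seconds), plus any covariate
#'   columns named in the spec. Missed trials must already be removed (see
#'   [run_inclusion_filters()]).
#' @return An object of class `ddm_model` with the parameter registry in
#'   `$params`; `nrow(model$params)` is the total parameter count.
#' @export
build_model <- function(spec, data) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  req <- c("subject_id", "group", "condition", "response", "rt")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    stop("`data` lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("`data` is empty.", call. = FALSE)
  if (anyNA(data$response) || anyNA(data$rt)) {
    stop("`data` contains missed trials; run run_inclusion_filters() first.",
         call. = FALSE)
  }
  for (cv in spec$covariates) {
    if (!cv %in% names(data)) {
      stop("Covariate column `", cv, "` not found in data.", call. = FALSE)
    }
    if (anyNA(data[[cv]])) {
      stop("Covariate `", cv, "` has missing values.", call. = FALSE)
    }
  }
  cond_chr <- as.character(data$condition)
  bad <- setdiff(unique(cond_chr), ant_conditions)
  if (length(bad) > 0) {
    stop("Unknown conditions in data: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  conditions <- ant_conditions[ant_conditions %in% unique(cond_chr)]
  groups <- unique(as.character(data$group))
  subjects <- data |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::mutate(group = as.character(.data$group))
  if (anyDuplicated(subjects$subject_id)) {
    stop("A subject appears in more than one group.", call. = FALSE)
  }
  # every subject needs at least one trial per represented condition
  cover <- table(data$subject_id, cond_chr)
  if (any(cover[, conditions, drop = FALSE] == 0)) {
    stop("Every subject needs >= 1 trial in each represented condition.",
         call. = FALSE)
  }

  reg <- list()
  add <- function(name, role, param, group = NA, subject = NA, cond = NA,
                  lower = -Inf, upper = Inf) {
    reg[[length(reg) + 1]] <<- tibble::tibble(
      name = name, role = role, param = param, group = group,
      subject = subject, cond = cond, lower = lower, upper = upper
    )
  }
  pr <- spec$priors
  eff_conds <- conditions[-1]  # treatment coding, congruent baseline
  for (g in groups) {
    add(sprintf("mu_v[%s]", g), "hyper_mu", "v", group = g)
    add(sprintf("sigma_v[%s]", g), "hyper_sigma", "v", group = g,
        lower = 1e-3, upper = 20)
    add(sprintf("mu_a[%s]", g), "hyper_mu", "a", group = g,
        lower = pr$mu_a$lower, upper = pr$mu_a$upper)
    add(sprintf("sigma_a[%s]", g), "hyper_sigma", "a", group = g,
        lower = 1e-3, upper = 20)
    add(sprintf("mu_t0[%s]", g), "hyper_mu", "t0", group = g,
        lower = pr$mu_t0$lower, upper = pr$mu_t0$upper)
    add(sprintf("sigma_t0[%s]", g), "hyper_sigma", "t0", group = g,
        lower = 1e-4, upper = 5)
    for (p in spec$varies) {
      for (cc in eff_conds) {
        add(sprintf("b_%s[%s,%s]", p, cc, g), "cond_effect", p, group = g,
            cond = cc)
      }
    }
    for (cv in spec$covariates) {
      add(sprintf("b_%s[%s]", cv, g), "cov_coef", cv, group = g)
    }
  }
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    g <- subjects$group[i]
    add(sprintf("v[%s]", sid), "subject", "v", group = g, subject = sid,
        lower = -20, upper = 20)
    add(sprintf("a[%s]", sid), "subject", "a", group = g, subject = sid,
        lower = 0.05, upper = 10)
    add(sprintf("t0[%s]", sid), "subject", "t0", group = g, subject = sid,
        lower = 0.01, upper = 2)
  }
  params <- dplyr::bind_rows(reg)

  pos <- function(nm) match(nm, params$name)
  subject_data <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    g <- subjects$group[i]
    d <- data[data$subject_id == sid, ]
    X <- if (length(spec$covariates) > 0) {
      as.matrix(d[, spec$covariates, drop = FALSE])
    } else {
      matrix(numeric(0), nrow = nrow(d), ncol = 0)
    }
    subject_data[[sid]] <- list(
      rt = as.numeric(d$rt), choice = as.integer(d$response),
      cond0 = match(as.character(d$condition), conditions) - 1L,
      X = X, group = g,
      iv = pos(sprintf("v[%s]", sid)),
      ia = pos(sprintf("a[%s]", sid)),
      it0 = pos(sprintf("t0[%s]", sid))
    )
  }
  group_index <- list()
  for (g in groups) {
    bv <- ba <- integer(0)
    if ("v" %in% spec$varies) {
      bv <- pos(sprintf("b_v[%s,%s]", eff_conds, g))
    }
    if ("a" %in% spec$varies) {
      ba <- pos(sprintf("b_a[%s,%s]", eff_conds, g))
    }
    bcov <- if (length(spec$covariates) > 0) {
      pos(sprintf("b_%s[%s]", spec$covariates, g))
    } else {
      integer(0)
    }
    group_index[[g]] <- list(
      bv = bv, ba = ba, bcov = bcov,
      mu_v = pos(sprintf("mu_v[%s]", g)),
      sigma_v = pos(sprintf("sigma_v[%s]", g)),
      mu_a = pos(sprintf("mu_a[%s]", g)),
      sigma_a = pos(sprintf("sigma_a[%s]", g)),
      mu_t0 = pos(sprintf("mu_t0[%s]", g)),
      sigma_t0 = pos(sprintf("sigma_t0[%s]", g)),
      subjects = subjects$subject_id[subjects$group == g]
    )
  }
  structure(
    list(spec = spec, data = data, subjects = subjects, groups = groups,
         conditions = conditions, params = params,
         subject_data = subject_data, group_index = group_index,
         n_trials = nrow(data)),
    class = "ddm_model"
  )
}

#' @export
print.ddm_model <- function(x, ...) {
  cat("<ddm_model> ", nrow(x$params), "parameters |",
      nrow(x$subjects), "subjects |", x$n_trials, "trials |",
      "varies:", paste(x$spec$varies, collapse = "+"), "\n")
  invisible(x)
}

# per-condition effect vectors (baseline entry 0) for group g under theta
group_effect_vectors <- function(model, theta, g) {
  gi <- model$group_index[[g]]
  nc <- length(model$conditions)
  bv <- ba <- numeric(nc)
  if (length(gi$bv) > 0) bv[-1] <- theta[gi$bv]
  if (length(gi$ba) > 0) ba[-1] <- theta[gi$ba]
  bcov <- if (length(gi$bcov) > 0) theta[gi$bcov] else numeric(0)
  list(bv = bv, ba = ba, bcov = bcov)
}

subject_loglik <- function(model, theta, sid) {
  sdat <- model$subject_data[[sid]]
  eff <- group_effect_vectors(model, theta, sdat$group)
  ddm_subject_loglik_cpp(
    sdat$rt, sdat$choice, sdat$cond0,
    theta[sdat$iv], theta[sdat$ia], theta[sdat$it0],
    eff$bv, eff$ba, sdat$X, eff$bcov,
    model$spec$z_rel, model$spec$p_outlier, model$spec$rt_max,
    model$spec$eps
  )
}

#' Total log-likelihood of a parameter assignment
#'
#' Sums the Wiener first-passage log density over all trials, with each
#' trial's drift and boundary resolved from its subject's baseline, the
#' group-level condition effects, and (when present) the group-level
#' covariate coefficients applied to the trial's covariate values.
#'
#' @param model A [build_model()] result.
#' @param params Named numeric vector covering every parameter in
#'   `model$params$name` (order free).
#' @return A single log-likelihood value.
#' @export
log_likelihood <- function(model, params) {
  stopifnot(inherits(model, "ddm_model"))
  if (is.null(names(params)) ||
      !all(model$params$name %in% names(params))) {
    stop("`params` must be a named vector covering model$params$name.",
         call. = FALSE)
  }
  theta <- unname(params[model$params$name])
  sum(vapply(names(model$subject_data),
             function(sid) subject_loglik(model, theta, sid),
             numeric(1)))
}
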