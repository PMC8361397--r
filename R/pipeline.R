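#' Apply the study inclusion filters
#'
#' Removes subjects who completed fewer than 5 or more than 6 runs, scored
#' below 70% correct on responded trials, or missed more than 10% of
#' trials; then drops the missed (no-response) trials of the retained
#' subjects. Boundary conventions: exactly 70% correct and exactly 10%
#' missed are retained.
#'
#' @param trials A cohort trial tibble (see [generate_cohort()]); must
#'   carry `run`, `response` and `missed` columns.
#' @param min_runs,max_runs Acceptable run-count range.
#' @param min_accuracy Minimum fraction correct among responded trials.
#' @param max_missed Maximum fraction of missed trials.
#' @return A list with `trials` (filtered tibble, missed trials removed)
#'   and `report` (per-subject tibble: `subject_id`, `group`, `n_runs`,
#'   `accuracy`, `missed_frac`, `excluded`, `reason`).
#' @export
run_inclusion_filters <- function(trials, min_runs = 5, max_runs = 6,
                                  min_accuracy = 0.70, max_missed = 0.10) {
  stopifnot(all(c("subject_id", "run", "response", "missed") %in%
                  names(trials)))
  report <- trials |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(
      n_runs = dplyr::n_distinct(.data$run),
      missed_frac = mean(.data$missed),
      accuracy = mean(.data$response[!.data$missed]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fail_runs = .data$n_runs < min_runs | .data$n_runs > max_runs,
      fail_accuracy = .data$accuracy < min_accuracy,
      fail_missed = .data$missed_frac > max_missed,
      excluded = .data$fail_runs | .data$fail_accuracy | .data$fail_missed,
      reason = dplyr::case_when(
        fail_runs ~ "run_count",
        fail_accuracy ~ "accuracy",
        fail_missed ~ "missed_responses",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::select("subject_id", "group", "n_runs", "accuracy",
                  "missed_frac", "excluded", "reason")
  keep <- report$subject_id[!report$excluded]
  out <- trials |>
    dplyr::filter(.data$subject_id %in% keep, !.data$missed)
  list(trials = out, report = report)
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end synthetic study: cohort and
#' schedule configuration, the MCMC preset, which model variants to
#' compare, and which trial-wise covariates enter the drift regression.
#'
#' @param group_specs Named list of [group_spec()] objects.
#' @param n_subjects_per_group Subjects per group.
#' @param schedule A [schedule_config()].
#' @param mcmc An [mcmc_config()].
#' @param variants Named list of `varies` arguments defining the model
#'   variants to compare by DIC.
#' @param covariates Covariate columns for the drift regression stage
#'   (empty vector to skip the stage).
#' @param p_outlier Contaminant weight used both in generation and fitting.
#' @param ppc_draws Posterior draws for the predictive check.
#' @param seed Master seed; each stage derives its own seed from it.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(group_specs = default_group_specs(),
                            n_subjects_per_group = 15,
                            schedule = schedule_config(),
                            mcmc = mcmc_config(),
                            variants = list(v_only = "v", a_only = "a",
                                            v_and_a = c("v", "a")),
                            covariates = c("beta_default", "beta_dorsal"),
                            p_outlier = 0.05,
                            ppc_draws = 500,
                            seed = 1,
                            out_dir = NULL) {
  structure(
    list(group_specs = group_specs,
         n_subjects_per_group = n_subjects_per_group, schedule = schedule,
         mcmc = mcmc, variants = variants, covariates = covariates,
         p_outlier = p_outlier, ppc_draws = ppc_draws, seed = seed,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

# fixed per-stage seed derivation from the master seed
stage_seed <- function(seed, offset) (seed * 97L + offset) %% 2000000000L

#' Run the end-to-end synthetic study
#'
#' Simulate a cohort, apply the inclusion filters, fit every configured
#' model variant, compare them by DIC, run a posterior predictive check on
#' the best variant, compute the group-contrast posterior-overlap matrix
#' (drift and boundary per condition, non-decision time overall), and fit
#' the trial-wise covariate regression with group-level coefficients. All
#' randomness derives from the master seed, and the report is stamped with
#' a hash of the configuration; two runs with the same configuration
#' produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @param progress Print stage progress.
#' @return An object of class `ddm_study`: list with `cohort`,
#'   `exclusions`, `fits`, `dic_table`, `best_variant`, `ppc`,
#'   `condition_posteriors`, `overlap`, `covariate_effects`, `config`,
#'   `config_hash`.
#' @export
run_study <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  note <- function(...) if (progress) message(...)
  hash <- rlang::hash(config[setdiff(names(config), "out_dir")])

  note("simulating cohort")
  cohort <- generate_cohort(config$group_specs, config$n_subjects_per_group,
                            config$schedule,
                            seed = stage_seed(config$seed, 11L),
                            p_outlier = config$p_outlier)
  filt <- run_inclusion_filters(cohort$trials)

  fits <- list()
  dic_rows <- list()
  for (vn in names(config$variants)) {
    note("fitting variant ", vn)
    spec <- ddm_model_spec(varies = config$variants[[vn]],
                           p_outlier = config$p_outlier,
                           rt_max = config$schedule$response_window)
    model <- build_model(spec, filt$trials)
    mc <- config$mcmc
    mc$seed <- stage_seed(config$seed, 23L + match(vn, names(config$variants)))
    fit <- sample_posterior(model, mc)
    d <- dic(fit)
    fits[[vn]] <- fit
    dic_rows[[vn]] <- tibble::tibble(
      variant = vn, varies = paste(config$variants[[vn]], collapse = "+"),
      dic = d$dic, p_d = d$p_d, mean_deviance = d$mean_deviance,
      max_rhat = max(gelman_rubin(fit)$rhat, na.rm = TRUE)
    )
  }
  dic_table <- dplyr::bind_rows(dic_rows)
  best <- dic_table$variant[which.min(dic_table$dic)]

  note("posterior predictive check on variant ", best)
  ppc <- posterior_predictive(fits[[best]], n_draws = config$ppc_draws,
                              seed = stage_seed(config$seed, 31L))

  note("group contrasts")
  cond_post <- reconstruct_condition_posteriors(fits[[best]])
  overlap <- condition_overlap_matrix(cond_post,
                                      seed = stage_seed(config$seed, 41L))

  cov_eff <- NULL
  if (length(config$covariates) > 0) {
    note("covariate regression")
    spec_cov <- ddm_model_spec(varies = config$variants[[best]],
                               covariates = config$covariates,
                               p_outlier = config$p_outlier,
                               rt_max = config$schedule$response_window)
    model_cov <- build_model(spec_cov, filt$trials)
    mc <- config$mcmc
    mc$seed <- stage_seed(config$seed, 53L)
    fit_cov <- sample_posterior(model_cov, mc)
    cov_eff <- covariate_effects(fit_cov)
    fits$covariate <- fit_cov
  }

  study <- structure(
    list(cohort = cohort, exclusions = filt$report, fits = fits,
         dic_table = dic_table, best_variant = best, ppc = ppc,
         condition_posteriors = cond_post, overlap = overlap,
         covariate_effects = cov_eff, config = config,
         config_hash = hash, seed = config$seed),
    class = "ddm_study"
  )
  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

#' Pairwise group posterior-overlap table
#'
#' Computes the posterior-overlap statistic for every pair of groups,
#' separately for drift rate and boundary in each condition and for the
#' non-decision time.
#'
#' @param cond_post Output of [reconstruct_condition_posteriors()].
#' @param seed Seed passed to [posterior_overlap()].
#' @param method Overlap method, see [posterior_overlap()].
#' @return A tibble: `parameter`, `condition`, `group_a`, `group_b`, `P`,
#'   `significant`.
#' @export
condition_overlap_matrix <- function(cond_post, seed = 1,
                                     method = "tail") {
  groups <- unique(cond_post$group)
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  cells <- cond_post |>
    dplyr::distinct(.data$parameter, .data$condition)
  purrr::map_dfr(pairs, function(pr) {
    purrr::pmap_dfr(cells, function(parameter, condition) {
      da <- cond_post$value[cond_post$group == pr[1] &
                              cond_post$parameter == parameter &
                              cond_post$condition == condition]
      db <- cond_post$value[cond_post$group == pr[2] &
                              cond_post$parameter == parameter &
                              cond_post$condition == condition]
      ov <- posterior_overlap(da, db, method = method, seed = seed)
      tibble::tibble(parameter = parameter, condition = condition,
                     group_a = pr[1], group_b = pr[2], P = ov$P,
                     significant = ov$significant)
    })
  })
}

#' Group-level covariate coefficient summaries
#'
#' For every covariate coefficient in a regression fit, reports the
#' posterior mean and the percentage of the posterior on the dominant side
#' of zero.
#'
#' @param fit A [sample_posterior()] result whose model includes
#'   covariates.
#' @return A tibble: `covariate`, `group`, `estimate`, `P`, `direction`,
#'   `significant`.
#' @export
covariate_effects <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  reg <- fit$model$params
  rows <- which(reg$role == "cov_coef")
  if (length(rows) == 0) {
    stop("The fitted model has no covariate coefficients.", call. = FALSE)
  }
  all_draws <- do.call(rbind, fit$draws)
  purrr::map_dfr(rows, function(i) {
    d <- all_draws[, reg$name[i]]
    pn <- prob_nonzero(d)
    tibble::tibble(covariate = reg$param[i], group = reg$group[i],
                   estimate = mean(d), P = pn$P,
                   direction = pn$direction, significant = pn$significant)
  })
}

#' @export
print.ddm_study <- function(x, ...) {
  cat("<ddm_study>  best variant:", x$best_variant, "\n")
  print(x$dic_table)
  invisible(x)
}

write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = study$config_hash, seed = study$seed)
  readr::write_csv(study$cohort$trials, file.path(dir, "trials.csv"))
  readr::write_csv(study$exclusions, file.path(dir, "exclusions.csv"))
  readr::write_csv(study$dic_table, file.path(dir, "dic_table.csv"))
  readr::write_csv(study$ppc$summary, file.path(dir, "ppc_summary.csv"))
  readr::write_csv(study$condition_posteriors,
                   file.path(dir, "condition_posteriors.csv"))
  readr::write_csv(study$overlap, file.path(dir, "overlap_matrix.csv"))
  if (!is.null(study$covariate_effects)) {
    readr::write_csv(study$covariate_effects,
                     file.path(dir, "covariate_effects.csv"))
  }
  jsonlite::write_json(
    c(stamp, list(best_variant = study$best_variant)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
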