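#' Posterior density plot of group-level parameters by condition
#'
#' Draws the per-condition group-level posterior densities of drift rate
#' and decision boundary (and non-decision time if requested), one panel
#' per parameter-condition cell, colour-coded by group.
#'
#' @param object A [sample_posterior()] result.
#' @param pars Which parameters to show (subset of `c("v", "a", "t0")`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddm_fit <- function(object, pars = c("v", "a"), ...) {
  cp <- reconstruct_condition_posteriors(object) |>
    dplyr::filter(.data$parameter %in% pars)
  ggplot2::ggplot(cp, ggplot2::aes(x = .data$value,
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::facet_grid(parameter ~ condition, scales = "free") +
    ggplot2::labs(x = "posterior value", y = "density",
                  colour = "group", fill = "group") +
    ggplot2::theme_minimal()
}

#' Posterior predictive check plot
#'
#' Observed summary statistics against their central 95% posterior
#' predictive intervals, per group and condition.
#'
#' @param object A [posterior_predictive()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddm_ppc <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$sim_mean,
                                          ymin = .data$sim_q025,
                                          ymax = .data$sim_q975),
                             colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "red", size = 2) +
    ggplot2::facet_grid(group ~ condition, scales = "free_y") +
    ggplot2::labs(y = "statistic value",
                  subtitle = "red: observed; grey: simulated 95% interval") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Covariate-coefficient posterior densities
#'
#' Densities of the group-level trial-wise covariate coefficients on drift
#' rate, one panel per covariate, colour-coded by group, with a reference
#' line at zero (the fraction of mass either side of which is the reported
#' P statistic).
#'
#' @param fit A [sample_posterior()] result with covariate coefficients.
#' @return A ggplot object.
#' @export
plot_coefficient_posteriors <- function(fit) {
  reg <- fit$model$params
  rows <- which(reg$role == "cov_coef")
  if (length(rows) == 0) {
    stop("The fitted model has no covariate coefficients.", call. = FALSE)
  }
  all_draws <- do.call(rbind, fit$draws)
  df <- purrr::map_dfr(rows, function(i) {
    tibble::tibble(covariate = reg$param[i], group = reg$group[i],
                   value = all_draws[, reg$name[i]])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~covariate, scales = "free") +
    ggplot2::labs(x = "coefficient (drift units per covariate SD)",
                  y = "density") +
    ggplot2::theme_minimal()
}
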