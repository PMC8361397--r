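#' Build a single-trial GLM design matrix
#'
#' One haemodynamic regressor per trial (a stick function at target onset
#' convolved with the canonical response, i.e. a shifted impulse response
#' sampled at the volume times), the six motion parameters as covariates of
#' no interest, an intercept, and a discrete-cosine high-pass basis for
#' periods above `high_pass` seconds. The number of cosine columns is
#' `floor(2 * run_length / high_pass)` where `run_length = n_volumes * TR`.
#'
#' @param run A `bold_run` object (or any list with `bold`, `events`,
#'   `motion` components of the same shape).
#' @param hrf Impulse-response function of time in seconds.
#' @param high_pass High-pass cutoff period in seconds (128 s by default).
#' @return An object of class `trial_design`: list with `X` (the design
#'   matrix with labelled columns), `roles` (column role labels: `trial`,
#'   `motion`, `intercept`, `cosine`), and `events`.
#' @export
build_trial_design <- function(run, hrf = canonical_hrf, high_pass = 128) {
  events <- run$events
  tv <- run$bold$time
  if (anyDuplicated(events$target_onset)) {
    stop("Duplicate event onsets in the design.", call. = FALSE)
  }
  if (max(events$target_onset) >= max(tv)) {
    stop("Event onset beyond run end.", call. = FALSE)
  }
  n <- length(tv)
  trials <- vapply(events$target_onset, function(o) hrf(tv - o),
                   numeric(n))
  colnames(trials) <- sprintf("trial_%02d", seq_len(nrow(events)))
  motion <- as.matrix(run$motion)
  tr <- tv[2] - tv[1]
  run_length <- n * tr
  n_cos <- floor(2 * run_length / high_pass)
  if (n_cos > 0) {
    idx <- seq_len(n) - 1
    cosines <- vapply(seq_len(n_cos), function(k) {
      sqrt(2 / n) * cos(pi * (2 * idx + 1) * k / (2 * n))
    }, numeric(n))
    colnames(cosines) <- sprintf("cosine_%02d", seq_len(n_cos))
  } else {
    cosines <- matrix(numeric(0), nrow = n, ncol = 0)
  }
  X <- cbind(trials, motion, intercept = 1, cosines)
  roles <- c(rep("trial", ncol(trials)), rep("motion", 6), "intercept",
             rep("cosine", ncol(cosines)))
  structure(list(X = X, roles = roles, events = events),
            class = "trial_design")
}

#' Estimate a single-trial beta series
#'
#' Scales the BOLD series to percent signal change (relative to the run mean
#' by default, or to a known `baseline`), optionally prewhitens with a
#' single-lag autoregressive model (coefficient pooled from the OLS
#' residuals of the run), and solves the single-trial GLM by least squares.
#' Returns one beta per modelled trial, in percent BOLD signal change.
#'
#' @param run A `bold_run` object.
#' @param design A [build_trial_design()] result; built from `run` when
#'   omitted.
#' @param whiten Apply AR(1) prewhitening before the solve.
#' @param baseline Optional known baseline intensity for the percent-signal
#'   scaling; the run mean is used when `NULL`.
#' @param ridge Ridge penalty used as a fallback (with a warning) when the
#'   design is rank-deficient.
#' @return A tibble with columns `trial_index` and `beta`, carrying the
#'   AR(1) coefficient (if estimated) as attribute `ar1`.
#' @export
fit_beta_series <- function(run, design = NULL, whiten = FALSE,
                            baseline = NULL, ridge = 1e-8) {
  if (is.null(design)) design <- build_trial_design(run)
  stopifnot(inherits(design, "trial_design"))
  y <- run$bold$bold
  if (any(!is.finite(y))) stop("Non-finite BOLD values.", call. = FALSE)
  ref <- if (is.null(baseline)) mean(y) else baseline
  y <- 100 * (y / ref - 1)
  X <- design$X
  solve_ls <- function(X, y) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      warning("Rank-deficient design; using ridge fallback.", call. = FALSE)
      b <- solve(crossprod(X) + diag(ridge, ncol(X)), crossprod(X, y))
      drop(b)
    } else {
      qr.coef(qx, y)
    }
  }
  beta <- solve_ls(X, y)
  rho <- NA_real_
  if (whiten) {
    res <- y - drop(X %*% beta)
    rho <- sum(res[-1] * res[-length(res)]) / sum(res^2)
    n <- length(y)
    Wy <- c(y[1] * sqrt(1 - rho^2), y[-1] - rho * y[-n])
    WX <- rbind(X[1, ] * sqrt(1 - rho^2), X[-1, ] - rho * X[-n, ])
    beta <- solve_ls(WX, Wy)
  }
  is_trial <- design$roles == "trial"
  out <- tibble::tibble(trial_index = seq_len(sum(is_trial)),
                        beta = unname(beta[is_trial]))
  attr(out, "ar1") <- rho
  out
}

#' Z-score a beta series
#'
#' Standardizes beta estimates to mean 0, SD 1 within a scope (per subject
#' across all runs' trials by default, or within any grouping columns given
#' by `by`), preserving row order.
#'
#' @param betas A tibble with a `beta` column.
#' @param by Optional character vector of grouping columns defining the
#'   standardization scope.
#' @return The input tibble with `beta` replaced by its z-scores.
#' @export
zscore_betas <- function(betas, by = NULL) {
  stopifnot("beta" %in% names(betas))
  zs <- function(x) {
    if (length(x) < 2) stop("Need >= 2 values to z-score.", call. = FALSE)
    s <- sd(x)
    if (s == 0) stop("Zero variance: degenerate beta series.", call. = FALSE)
    (x - mean(x)) / s
  }
  if (is.null(by)) {
    betas$beta <- zs(betas$beta)
    betas
  } else {
    betas |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::mutate(beta = zs(.data$beta)) |>
      dplyr::ungroup()
  }
}
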