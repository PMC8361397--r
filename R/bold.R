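#' Canonical haemodynamic response function
#'
#' Double-gamma impulse response: a positive gamma response peaking around
#' 5 s minus a later undershoot gamma (peak around 15-16 s) scaled by
#' `undershoot_ratio`, with the overall peak normalized to 1. The response
#' is causal: zero at and before `t = 0`.
#'
#' @param t Time grid in seconds (spacing > 0).
#' @param peak_shape,peak_rate Shape/rate of the response gamma (peak at
#'   `(peak_shape - 1) / peak_rate` = 5 s with the defaults).
#' @param undershoot_shape,undershoot_rate Shape/rate of the undershoot
#'   gamma (peak at 15 s with the defaults).
#' @param undershoot_ratio Relative undershoot amplitude.
#' @return Numeric vector of responses, unit peak.
#' @examples
#' h <- canonical_hrf(seq(0, 32, 0.1))
#' @export
canonical_hrf <- function(t, peak_shape = 6, peak_rate = 1,
                          undershoot_shape = 16, undershoot_rate = 1,
                          undershoot_ratio = 1 / 6) {
  h <- dgamma(t, peak_shape, peak_rate) -
    undershoot_ratio * dgamma(t, undershoot_shape, undershoot_rate)
  h[t <= 0] <- 0
  # peak value of the same parameterization on a fine reference grid
  tref <- seq(0, 32, by = 0.01)
  href <- dgamma(tref, peak_shape, peak_rate) -
    undershoot_ratio * dgamma(tref, undershoot_shape, undershoot_rate)
  h / max(href)
}

#' BOLD-run generating configuration
#'
#' Parameters for synthesizing one run's network-averaged BOLD series at the
#' acquisition geometry of the study (TR 1.92 s, 156 volumes). All signal
#' components are expressed in percent of the baseline intensity.
#'
#' @param tr Repetition time in seconds.
#' @param n_volumes Volumes per run.
#' @param baseline Baseline intensity in scanner units.
#' @param noise_sd SD of the AR(1) measurement noise (percent signal).
#'   The default reflects a network-averaged time course, whose thermal
#'   noise is strongly suppressed by averaging over many voxels.
#' @param noise_ar Lag-1 autocorrelation of the noise.
#' @param drift_amplitude Amplitude of the slow scanner drift (percent
#'   signal); the drift is a sum of cosines with periods well above the
#'   128 s high-pass cutoff.
#' @param drift_periods Periods (seconds) of the drift cosines.
#' @param motion_sd Innovation SD of the random-walk motion parameters
#'   (mm for translations, degrees for rotations).
#' @param motion_leak SD of the per-column coefficients leaking motion into
#'   the BOLD series (percent signal per motion unit).
#' @param n_voxels Optional number of synthetic voxels for a voxel-by-time
#'   matrix (0 = network average only).
#' @return An object of class `bold_run_config`.
#' @export
bold_run_config <- function(tr = 1.92, n_volumes = 156, baseline = 100,
                            noise_sd = 0.4, noise_ar = 0.3,
                            drift_amplitude = 1.0,
                            drift_periods = c(200, 300),
                            motion_sd = 0.02, motion_leak = 0.5,
                            n_voxels = 0) {
  stopifnot(tr > 0, n_volumes > 1, baseline > 0, noise_sd >= 0,
            abs(noise_ar) < 1, n_voxels >= 0)
  structure(
    list(tr = tr, n_volumes = n_volumes, baseline = baseline,
         noise_sd = noise_sd, noise_ar = noise_ar,
         drift_amplitude = drift_amplitude, drift_periods = drift_periods,
         motion_sd = motion_sd, motion_leak = motion_leak,
         n_voxels = n_voxels),
    class = "bold_run_config"
  )
}

#' Synthesize one run of network-averaged BOLD data
#'
#' The time course is the sum of per-trial haemodynamic responses (stick
#' events at target onset scaled by the per-trial amplitudes in percent
#' signal change), a slow drift, a linear leakage of the six motion
#' regressors, and AR(1) noise, all modulating the baseline intensity.
#' Ground-truth amplitudes are returned for recovery testing.
#'
#' @param events A tibble with a `target_onset` column in seconds (one row
#'   per trial), e.g. one run of [generate_trial_schedule()].
#' @param amplitudes Per-trial true response amplitudes (percent signal
#'   change); length must equal `nrow(events)`.
#' @param config A [bold_run_config()].
#' @param seed Integer seed.
#' @return An object of class `bold_run`: list with `bold` (tibble `time`,
#'   `bold`), `events`, `motion` (156 x 6 tibble, columns `trans_x..z`,
#'   `rot_x..z`), `amplitudes`, `config`, and (if `n_voxels > 0`) `voxels`,
#'   a voxel-by-time matrix.
#' @export
generate_bold_run <- function(events, amplitudes,
                              config = bold_run_config(), seed = NULL) {
  stopifnot(inherits(config, "bold_run_config"))
  if (!"target_onset" %in% names(events)) {
    stop("`events` must have a `target_onset` column.", call. = FALSE)
  }
  if (length(amplitudes) != nrow(events)) {
    stop("`amplitudes` must have one value per event.", call. = FALSE)
  }
  tv <- (seq_len(config$n_volumes) - 1) * config$tr
  if (max(events$target_onset) >= max(tv)) {
    stop("Events extend beyond the run duration.", call. = FALSE)
  }
  build <- function() {
    sig <- numeric(length(tv))
    for (k in seq_along(amplitudes)) {
      sig <- sig + amplitudes[k] * canonical_hrf(tv - events$target_onset[k])
    }
    drift <- numeric(length(tv))
    for (p in config$drift_periods) {
      drift <- drift + cos(2 * pi * tv / p)
    }
    drift <- config$drift_amplitude * drift
    motion <- matrix(rnorm(6 * length(tv), 0, config$motion_sd),
                     ncol = 6)
    motion <- apply(motion, 2, cumsum)
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    leak_coef <- rnorm(6, 0, config$motion_leak)
    leak <- drop(motion %*% leak_coef)
    eps <- rnorm(length(tv), 0, config$noise_sd)
    if (config$noise_ar != 0 && config$noise_sd > 0) {
      eps <- as.numeric(stats::filter(eps, config$noise_ar,
                                      method = "recursive"))
      eps <- eps * sqrt(1 - config$noise_ar^2)
    }
    pct <- sig + drift + leak + eps
    bold <- config$baseline * (1 + pct / 100)
    out <- list(
      bold = tibble::tibble(time = tv, bold = bold),
      events = events,
      motion = tibble::as_tibble(motion),
      amplitudes = amplitudes,
      config = config
    )
    if (config$n_voxels > 0) {
      vox <- matrix(rnorm(config$n_voxels * length(tv), 0, config$noise_sd),
                    nrow = config$n_voxels, byrow = TRUE)
      vox <- sweep(vox, 2, sig + drift + leak, "+")
      out$voxels <- config$baseline * (1 + vox / 100)
    }
    structure(out, class = "bold_run")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @export
print.bold_run <- function(x, ...) {
  cat("<bold_run> ", nrow(x$bold), "volumes @ TR", x$config$tr, "s,",
      nrow(x$events), "events\n")
  invisible(x)
}
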