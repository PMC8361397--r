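#' Frame-to-frame motion summary
#'
#' Computes absolute first differences of the six realignment parameters and
#' summarizes translations (mm) and rotations (degrees) by their mean and
#' maximum over all frame transitions and axes.
#'
#' @param motion A data frame or matrix with six columns: three translations
#'   followed by three rotations (as produced by [generate_bold_run()]).
#' @return A one-row tibble: `mean_translation`, `max_translation`,
#'   `mean_rotation`, `max_rotation`.
#' @export
qc_motion <- function(motion) {
  m <- as.matrix(motion)
  if (nrow(m) < 2 || ncol(m) != 6) {
    stop("`motion` must have >= 2 frames and 6 columns.", call. = FALSE)
  }
  d <- abs(diff(m))
  tibble::tibble(
    mean_translation = mean(d[, 1:3]),
    max_translation = max(d[, 1:3]),
    mean_rotation = mean(d[, 4:6]),
    max_rotation = max(d[, 4:6])
  )
}

#' Standardized DVARS of an image series
#'
#' DVARS is the root-mean-square over voxels of the temporal derivative at
#' each frame transition (the per-image standard deviation of the temporal
#' derivative). The standardized variant divides by a robust estimate of the
#' expected frame-difference standard deviation (half the interquartile
#' range of all frame differences, scaled to the normal), so that a
#' stationary-noise series averages approximately 1 and the result is
#' invariant to global intensity scaling.
#'
#' @param frames A voxel-by-time numeric matrix (>= 1 voxel, >= 2 frames).
#' @return A list with `series` (tibble: `transition`, `raw`,
#'   `standardized`) and `mean_dvars` (run mean of the standardized series).
#' @export
qc_dvars <- function(frames) {
  f <- as.matrix(frames)
  if (ncol(f) < 2) stop("Need >= 2 time points.", call. = FALSE)
  d <- f[, -1, drop = FALSE] - f[, -ncol(f), drop = FALSE]
  raw <- sqrt(colMeans(d^2))
  # robust SD of frame differences: half-IQR scaled to the normal
  sd_robust <- (stats::IQR(as.numeric(d)) / 2) / qnorm(0.75)
  standardized <- if (sd_robust > 0) raw / sd_robust else rep(NA_real_,
                                                              length(raw))
  list(
    series = tibble::tibble(transition = seq_along(raw), raw = raw,
                            standardized = standardized),
    mean_dvars = mean(standardized)
  )
}
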