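#' Drift-diffusion parameter set for one subject-condition
#'
#' Bundles the parameters of a single Wiener diffusion decision process under
#' the unit diffusion-scale convention (`s = 1`; parameter magnitudes are not
#' comparable to values quoted under the alternative `s = 0.1` convention).
#' Evidence accumulates from a starting point `z_rel * a` at mean rate `v`
#' until it is absorbed at the upper boundary `a` (coded as the correct
#' response) or the lower boundary 0 (error). A response is emitted a
#' non-decision time `t0` after absorption. A fraction `p_outlier` of
#' responses are contaminants: uniform on `(0, rt_max)` with a fair coin for
#' the choice, representing lapses that carry no decision information.
#'
#' @param v Drift rate (evidence units per second).
#' @param a Boundary separation (> 0).
#' @param z_rel Relative starting point in (0, 1); 0.5 encodes no response
#'   bias and is the only value used by the fitting routines.
#' @param t0 Non-decision time in seconds (>= 0).
#' @param p_outlier Contaminant mixture weight in `[0, 1)`.
#' @param rt_max Upper support of the contaminant distribution in seconds;
#'   defaults to the 3 s task response window. Must exceed `t0`.
#'
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(v = 1, a = 2, t0 = 0.3)
#' @export
ddm_params <- function(v, a, z_rel = 0.5, t0 = 0, p_outlier = 0,
                       rt_max = 3) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("`a` must be a single positive number.", call. = FALSE)
  }
  if (!is.numeric(z_rel) || length(z_rel) != 1L || z_rel <= 0 || z_rel >= 1) {
    stop("`z_rel` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) || t0 < 0) {
    stop("`t0` must be a single non-negative number.", call. = FALSE)
  }
  if (!is.numeric(p_outlier) || length(p_outlier) != 1L ||
      p_outlier < 0 || p_outlier >= 1) {
    stop("`p_outlier` must lie in [0, 1).", call. = FALSE)
  }
  if (!is.numeric(rt_max) || length(rt_max) != 1L || rt_max <= t0) {
    stop("`rt_max` must exceed `t0`.", call. = FALSE)
  }
  structure(
    list(v = v, a = a, z_rel = z_rel, t0 = t0, p_outlier = p_outlier,
         rt_max = rt_max),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("<ddm_params>  v =", format(x$v), " a =", format(x$a),
      " z_rel =", format(x$z_rel), " t0 =", format(x$t0),
      " p_outlier =", format(x$p_outlier), "\n")
  invisible(x)
}

is_ddm_params <- function(x) inherits(x, "ddm_params")

assert_ddm_params <- function(params) {
  if (!is_ddm_params(params)) {
    stop("`params` must be created with ddm_params().", call. = FALSE)
  }
  invisible(params)
}
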