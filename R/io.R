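#' Read and write trial tables
#'
#' Trial tables round-trip through CSV with reaction times written at full
#' precision (at least six decimal digits). Conditions are restored as a
#' factor with the canonical level order on read.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a tibble.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("condition" %in% names(out)) {
    out$condition <- factor(out$condition, levels = ant_conditions)
  }
  out
}

#' Persist posterior draws to a columnar CSV
#'
#' Writes the retained draws in long format (`chain`, `.iteration`,
#' `parameter`, `value`), the standard columnar layout for draw archives.
#'
#' @param fit A [sample_posterior()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  readr::write_csv(posterior_draws(fit), path)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
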