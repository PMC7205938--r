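#' Tidy an input-function fit
#'
#' @param x An `aif_fit` from [fit_aif()].
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`, `estimate`),
#'   including the solved breakpoints `t0` and `t1`.
#' @export
tidy.aif_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("a", "b", "c1", "c2", "d1", "d2", "t0", "t1"),
    estimate = c(p$a, p$b, p$c1, p$c2, p$d1, p$d2, p$t0, p$t1)
  )
}

#' Glance at an input-function fit
#'
#' @param x An `aif_fit` from [fit_aif()].
#' @param ... Unused.
#' @return A one-row tibble: `r.squared`, `sigma` (residual standard
#'   deviation), `nobs`.
#' @export
glance.aif_fit <- function(x, ...) {
  res <- x$data$concentration - x$fitted
  tibble(
    r.squared = x$r_squared,
    sigma = sqrt(sum(res^2) / max(1, length(res) - 6)),
    nobs = length(res)
  )
}

#' Tidy an NECR experiment
#'
#' @param x A `necr_experiment` from [necr_experiment()].
#' @param ... Unused.
#' @return The per-window points tibble with the source position appended.
#' @export
tidy.necr_experiment <- function(x, ...) {
  out <- x$points
  out$y_cm <- x$position[2]
  out
}

#' Glance at an NECR experiment
#'
#' @param x A `necr_experiment`.
#' @param ... Unused.
#' @return One-row tibble: `necr_max`, `activity_at_max_mbq`, `n_decays`.
#' @export
glance.necr_experiment <- function(x, ...) {
  tibble(necr_max = x$necr_max,
         activity_at_max_mbq = x$activity_at_max_mbq,
         n_decays = x$n_decays)
}
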