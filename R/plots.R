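#' Plot a count-rate curve
#'
#' Singles, prompts, trues, scatters and randoms rates against time.
#'
#' @param object A `count_rate_curve` from [bin_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.count_rate_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("t_mid", "singles", "prompts", "trues",
                          "scatters", "randoms")],
    -"t_mid", names_to = "class", values_to = "rate"
  )
  ggplot(long, aes(x = .data$t_mid, y = .data$rate,
                   colour = .data$class)) +
    geom_line() +
    labs(x = "time (s)", y = "rate (cps)", colour = NULL)
}

#' Plot an NECR experiment
#'
#' NECR against source activity, with the interpolated peak marked.
#'
#' @param object A `necr_experiment` from [necr_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.necr_experiment <- function(object, ...) {
  ggplot(object$points, aes(x = .data$activity_mbq, y = .data$necr)) +
    geom_line() + geom_point() +
    ggplot2::annotate("point", x = object$activity_at_max_mbq,
                      y = object$necr_max, shape = 4, size = 3) +
    scale_x_log10() +
    labs(x = "activity (MBq)", y = "NECR (cps)")
}

#' Plot an input-function curve
#'
#' @param object An `aif_curve` from [aif_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aif_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time_s, y = .data$concentration)) +
    geom_line() +
    labs(x = "time (s)",
         y = sprintf("concentration (%s)", attr(object, "unit") %||% ""))
}

#' Plot a ring-scaling gain table
#'
#' Sensitivities against the number of axial detection rings.
#'
#' @param object A `gain_table` from [gain_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gain_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("n_rings", "sensitivity_singles",
                          "sensitivity_coincidences")],
    -"n_rings", names_to = "quantity", values_to = "sensitivity"
  )
  ggplot(long, aes(x = .data$n_rings, y = .data$sensitivity,
                   colour = .data$quantity)) +
    geom_line() + geom_point() +
    labs(x = "axial rings", y = "sensitivity (cps/kBq)", colour = NULL)
}
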