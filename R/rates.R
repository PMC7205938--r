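#' Noise-equivalent count rate
#'
#' `NECR = T^2 / (T + S + k * R)`, the standard signal-to-noise figure of
#' merit for coincidence counting; 0 when the trues rate is 0.
#'
#' @param trues,scatters,randoms Rates in cps (non-negative; vectorised).
#' @param k Randoms weighting factor (1 for this detector's direct
#'   randoms estimate).
#' @return NECR in cps.
#' @examples
#' necr(100, 50, 50)  # 50
#' @export
necr <- function(trues, scatters, randoms, k = 1) {
  if (any(trues < 0) || any(scatters < 0) || any(randoms < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  den <- trues + scatters + k * randoms
  ifelse(den > 0, trues^2 / den, 0)
}

#' Bin an event stream into count-rate curves
#'
#' @param sim A `coincidence_sim` from [simulate_run()], or a list with
#'   elements `singles` and `coincidences`.
#' @param bin_width Bin width, s.
#' @param t_range Optional length-2 time range; defaults to the simulated
#'   source span.
#' @return A tibble of class `count_rate_curve` with columns `t_lo`,
#'   `t_hi`, `t_mid` and per-bin rates in cps: `singles`, `prompts`,
#'   `trues`, `scatters`, `randoms`.  `prompts = trues + scatters +
#'   randoms` holds exactly in every bin.
#' @export
bin_rates <- function(sim, bin_width = 1, t_range = NULL) {
  .assert_scalar_num(bin_width, "bin_width", lower = 0, allow_zero = FALSE)
  t_range <- t_range %||% sim$t_range %||%
    c(0, max(1, sim$singles$time, na.rm = TRUE))
  edges <- seq(t_range[1], t_range[2] + bin_width * 0.999999,
               by = bin_width)
  if (length(edges) < 2L) edges <- c(t_range[1], t_range[1] + bin_width)
  nb <- length(edges) - 1L
  cnt <- function(t) {
    idx <- findInterval(t, edges, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  }
  co <- sim$coincidences
  is_cls <- function(cl) co$class == cl
  out <- tibble(
    t_lo = edges[-length(edges)], t_hi = edges[-1],
    t_mid = (edges[-length(edges)] + edges[-1]) / 2,
    singles = cnt(sim$singles$time) / bin_width,
    trues = cnt(co$t1[is_cls("true")]) / bin_width,
    scatters = cnt(co$t1[is_cls("scattered")]) / bin_width,
    randoms = cnt(co$t1[is_cls("random")]) / bin_width
  )
  out$prompts <- out$trues + out$scatters + out$randoms
  out <- out[, c("t_lo", "t_hi", "t_mid", "singles", "prompts", "trues",
                 "scatters", "randoms")]
  attr(out, "bin_width") <- bin_width
  class(out) <- c("count_rate_curve", class(out))
  out
}

#' Detection sensitivity
#'
#' @param counts Total detected counts.
#' @param activity_kbq Mean source activity over the acquisition, kBq.
#' @param duration_s Acquisition duration, s.
#' @return Sensitivity in cps/kBq.
#' @export
sensitivity <- function(counts, activity_kbq, duration_s) {
  .assert_scalar_num(activity_kbq, "activity_kbq", lower = 0,
                     allow_zero = FALSE)
  .assert_scalar_num(duration_s, "duration_s", lower = 0, allow_zero = FALSE)
  (counts / duration_s) / activity_kbq
}

#' Fraction of singles on a block subset
#'
#' @param x A singles tibble (column `block`) or a per-block histogram
#'   tibble with columns `block` and `n`.
#' @param subset Integer block ids (for multi-ring scanners, global ids).
#' @return Fraction of all singles recorded on `subset`, in `[0, 1]`.
#' @examples
#' h <- tibble::tibble(block = 1:14, n = 10)
#' singles_fraction(h, 4:11)  # 8/14
#' @export
singles_fraction <- function(x, subset) {
  stopifnot(is.data.frame(x))
  if (!"n" %in% names(x)) x <- count(x, .data$block)
  total <- sum(x$n)
  if (total == 0) stop("empty histogram", call. = FALSE)
  sum(x$n[x$block %in% subset]) / total
}

# quadratic-interpolation peak through the three samples around the max;
# falls back to the max sample at the edges or for non-concave fits
.quad_peak <- function(x, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) {
    return(list(x = x[i], y = y[i]))
  }
  xs <- x[(i - 1):(i + 1)]; ys <- y[(i - 1):(i + 1)]
  fit <- lm(ys ~ xs + I(xs^2))
  a2 <- coef(fit)[3]
  if (!is.finite(a2) || a2 >= 0) return(list(x = x[i], y = y[i]))
  xv <- -coef(fit)[2] / (2 * a2)
  if (xv < xs[1] || xv > xs[3]) return(list(x = x[i], y = y[i]))
  yv <- sum(coef(fit) * c(1, xv, xv^2))
  list(x = unname(xv), y = unname(yv))
}

#' Decaying-point-source NECR experiment
#'
#' Simulates a decaying source in a water phantom over a schedule of
#' acquisition windows (see [point_source_timeline()]), computes per-window
#' trues/scatters/randoms/singles rates and NECR, and locates the NECR peak
#' by quadratic interpolation around the maximum sample (on log10 activity).
#'
#' @param scanner A `scanner_config`.
#' @param phantom A [phantom_model()]; default 8-cm water cylinder.
#' @param position Source position (x, y, z), cm.
#' @param a0 Start activity, Bq (default 14 MBq).
#' @param half_life Source half-life, s (default F-18).
#' @param n_windows,n_half_lives,histories_per_window Schedule parameters,
#'   see [point_source_timeline()].
#' @param seed Optional seed.
#' @return An object of class `necr_experiment`: list with `points`
#'   (tibble: `window`, `activity_mbq`, `duration`, `singles`, `trues`,
#'   `scatters`, `randoms`, `prompts` in cps, `necr`), `necr_max`,
#'   `activity_at_max_mbq`, `position`, `n_decays`.
#' @export
necr_experiment <- function(scanner, phantom = build_water_phantom(),
                            position = c(0, -1, 0), a0 = 14e6,
                            half_life = 6586.2, n_windows = 20,
                            n_half_lives = 5, histories_per_window = 1e5,
                            seed = NULL) {
  .assert_scalar_num(a0, "a0", lower = 0, allow_zero = FALSE)
  tl <- point_source_timeline(position, a0, half_life,
                              n_windows = n_windows,
                              n_half_lives = n_half_lives,
                              histories_per_window = histories_per_window)
  windows <- attr(tl, "windows")
  sim <- simulate_run(tl, phantom, scanner, seed = seed)
  win_of <- function(t) findInterval(t, windows$t_lo)
  s_cnt <- tabulate(win_of(sim$singles$time), nbins = n_windows)
  co <- sim$coincidences
  c_cnt <- function(cl) {
    tabulate(win_of(co$t1[co$class == cl]), nbins = n_windows)
  }
  pts <- tibble(
    window = windows$window,
    activity_mbq = windows$activity / 1e6,
    duration = windows$duration,
    singles = s_cnt / windows$duration,
    trues = c_cnt("true") / windows$duration,
    scatters = c_cnt("scattered") / windows$duration,
    randoms = c_cnt("random") / windows$duration
  )
  pts$prompts <- pts$trues + pts$scatters + pts$randoms
  pts$necr <- necr(pts$trues, pts$scatters, pts$randoms)
  pk <- .quad_peak(log10(pts$activity_mbq), pts$necr)
  structure(
    list(points = pts, necr_max = pk$y, activity_at_max_mbq = 10^pk$x,
         position = position, n_decays = sim$n_decays, seed = seed),
    class = "necr_experiment"
  )
}

#' @export
print.necr_experiment <- function(x, ...) {
  cat(sprintf("<necr_experiment> source at (%g, %g, %g) cm: NECRmax %.3g cps at %.3g MBq (%s decays)\n",
              x$position[1], x$position[2], x$position[3],
              x$necr_max, x$activity_at_max_mbq,
              format(x$n_decays, big.mark = ",")))
  invisible(x)
}

#' Gain table across detector-ring configurations
#'
#' Compares runs of the same source with different numbers of axial
#' detection rings against a reference run (by default the run with the
#' fewest rings): ratios of peak singles and peak coincidence rates (on the
#' runs' rate-curve bins) plus absolute sensitivities in cps/kBq.
#'
#' @param runs List of `btac_run` results from [run_btac_experiment()] (or
#'   any list with elements `n_rings`, `rates` (a [bin_rates()] curve),
#'   `singles_total`, `coincidences_total`, `duration`,
#'   `mean_activity_kbq`).
#' @param reference Optional reference run (defaults to the entry with the
#'   fewest rings).
#' @return A tibble of class `gain_table`: `n_rings`, `peak_singles`,
#'   `peak_coincidences` (cps), `singles_gain`, `coincidence_gain`,
#'   `sensitivity_singles`, `sensitivity_coincidences` (cps/kBq).
#' @export
gain_table <- function(runs, reference = NULL) {
  stopifnot(is.list(runs), length(runs) >= 1L)
  tracers <- vapply(runs, function(r) r$tracer %||% "", character(1))
  if (length(unique(tracers)) > 1L) {
    stop("runs use different tracers", call. = FALSE)
  }
  row_of <- function(r) {
    tibble(
      n_rings = r$n_rings,
      peak_singles = max(r$rates$singles),
      peak_coincidences = max(r$rates$prompts),
      sensitivity_singles = sensitivity(r$singles_total,
                                        r$mean_activity_kbq, r$duration),
      sensitivity_coincidences = sensitivity(r$coincidences_total,
                                             r$mean_activity_kbq, r$duration)
    )
  }
  tab <- bind_rows(lapply(runs, row_of)) |> arrange(.data$n_rings)
  ref <- if (is.null(reference)) tab[1L, ] else row_of(reference)
  tab$singles_gain <- tab$peak_singles / ref$peak_singles
  tab$coincidence_gain <- tab$peak_coincidences / ref$peak_coincidences
  out <- tab[, c("n_rings", "peak_singles", "peak_coincidences",
                 "singles_gain", "coincidence_gain", "sensitivity_singles",
                 "sensitivity_coincidences")]
  class(out) <- c("gain_table", class(out))
  out
}
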