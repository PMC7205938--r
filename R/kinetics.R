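#' Parameters of the piecewise linear-exponential input-function model
#'
#' The blood time-activity curve (BTAC) model used throughout the package is
#' zero up to `t0`, a linear ramp `a*t + b` on `(t0, t1)` and a
#' bi-exponential tail `c1*exp(d1*t) + c2*exp(d2*t)` from `t1` on.  Decay
#' constants `d1`, `d2` are stored exactly as fitted (negative values give a
#' decaying tail).  When `t0`/`t1` are not supplied they are derived with
#' [solve_breakpoints()]: `t0` is the (clamped) zero crossing of the ramp
#' and `t1` the first ramp/tail intersection, which makes the curve
#' continuous at `t1` by construction.
#'
#' @param a Ramp slope, concentration/s (must be non-zero when breakpoints
#'   are to be solved).
#' @param b Ramp intercept, concentration.
#' @param c1,c2 Tail amplitudes, concentration.
#' @param d1,d2 Tail rate constants, 1/s (negative for a decaying tail).
#' @param t0,t1 Optional breakpoints, s; solved when `NULL`.
#' @param unit Concentration unit tag, `"kBq/ml"` (default) or `"Bq/ml"`.
#' @param horizon Search horizon for the ramp/tail intersection, s.
#' @return An object of class `aif_params`.
#' @examples
#' p <- aif_params(1, -10, 20, 0, 0, 0)  # t0 = 10, t1 = 30
#' aif_value(p, c(5, 20, 40))
#' @export
aif_params <- function(a, b, c1, c2, d1, d2, t0 = NULL, t1 = NULL,
                       unit = c("kBq/ml", "Bq/ml"), horizon = 600) {
  unit <- match.arg(unit)
  for (nm in c("a", "b", "c1", "c2", "d1", "d2")) {
    .assert_scalar_num(get(nm), nm)
  }
  p <- structure(list(a = a, b = b, c1 = c1, c2 = c2, d1 = d1, d2 = d2,
                      t0 = t0, t1 = t1, unit = unit),
                 class = "aif_params")
  if (is.null(t0) || is.null(t1)) {
    bp <- solve_breakpoints(p, horizon = horizon)
    p$t0 <- unname(bp["t0"]); p$t1 <- unname(bp["t1"])
  }
  if (p$t1 < p$t0) stop("t1 must be >= t0", call. = FALSE)
  p
}

#' @export
print.aif_params <- function(x, ...) {
  cat(sprintf("<aif_params> [%s] a=%.4g b=%.4g c1=%.4g c2=%.4g d1=%.4g d2=%.4g | t0=%.4g s t1=%.4g s\n",
              x$unit, x$a, x$b, x$c1, x$c2, x$d1, x$d2, x$t0, x$t1))
  invisible(x)
}

#' Solve the breakpoints of the input-function model
#'
#' `t0 = max(0, -b/a)` is the zero crossing of the ramp, clamped at zero;
#' `t1` is the smallest `t > t0` where the ramp meets the tail, located by a
#' sign-change scan followed by bisection to 1e-9 relative tolerance.  If
#' the ramp is already at or above the tail at `t0`, `t1 = t0` (no linear
#' section).
#'
#' @param params An [aif_params()] object or bare list with fields
#'   `a`, `b`, `c1`, `c2`, `d1`, `d2`.
#' @param horizon Search horizon, s.
#' @return Named numeric `c(t0 = , t1 = )`.
#' @export
solve_breakpoints <- function(params, horizon = 600) {
  a <- params$a; b <- params$b
  c1 <- params$c1; c2 <- params$c2; d1 <- params$d1; d2 <- params$d2
  if (a == 0) stop("ramp slope `a` must be non-zero", call. = FALSE)
  t0 <- max(0, -b / a)
  g <- function(t) (a * t + b) - (c1 * exp(d1 * t) + c2 * exp(d2 * t))
  if (g(t0) >= 0) return(c(t0 = t0, t1 = t0))
  if (t0 >= horizon) stop("no ramp/tail intersection before the horizon",
                          call. = FALSE)
  grid <- seq(t0, horizon, length.out = 4096L)
  gv <- g(grid)
  idx <- which(gv[-1] >= 0 & gv[-length(gv)] < 0)
  if (length(idx) == 0L) {
    stop("no ramp/tail intersection before the horizon", call. = FALSE)
  }
  root <- uniroot(g, lower = grid[idx[1]], upper = grid[idx[1] + 1L],
                  tol = 1e-9 * max(1, grid[idx[1] + 1L]))
  c(t0 = t0, t1 = root$root)
}

#' Evaluate the input-function model
#'
#' @param params An [aif_params()] object.
#' @param t Numeric vector of times, s.
#' @return Concentrations (same unit as `params`), clamped at zero.
#' @export
aif_value <- function(params, t) {
  stopifnot(inherits(params, "aif_params"), is.numeric(t), all(is.finite(t)))
  v <- numeric(length(t))
  ramp <- t > params$t0 & t < params$t1
  tail_ <- t >= params$t1
  v[ramp] <- params$a * t[ramp] + params$b
  v[tail_] <- params$c1 * exp(params$d1 * t[tail_]) +
    params$c2 * exp(params$d2 * t[tail_])
  pmax(0, v)
}

#' Tracer definition: nuclide constants plus arterial and venous curves
#'
#' @param name Tracer name.
#' @param half_life Physical half-life, s.
#' @param injected_activity_mbq Nominal injected activity, MBq (metadata).
#' @param arterial,venous [aif_params()] for the arterial input function and
#'   the dispersed venous output function.
#' @param venous_delay Extra time shift applied to the venous curve, s.
#' @return An object of class `tracer_spec`.
#' @export
tracer_spec <- function(name, half_life, injected_activity_mbq,
                        arterial, venous, venous_delay = 5) {
  stopifnot(is.character(name), inherits(arterial, "aif_params"),
            inherits(venous, "aif_params"))
  .assert_scalar_num(half_life, "half_life", lower = 0, allow_zero = FALSE)
  .assert_scalar_num(venous_delay, "venous_delay", lower = 0)
  structure(list(name = name, half_life = half_life,
                 injected_activity_mbq = injected_activity_mbq,
                 arterial = arterial, venous = venous,
                 venous_delay = venous_delay),
            class = "tracer_spec")
}

#' Shipped tracer library
#'
#' Curve parameters for O-15 labelled water (1000 MBq nominal injection)
#' and F-18 fallypride (250 MBq), fitted to clinical arterial-sampler data
#' with the linear-exponential model; concentrations in kBq/ml.  Venous
#' curves are the dispersed fits, applied with an additional 5 s delay.
#' Half-lives: O-15 122.24 s, F-18 6586.2 s (standard nuclear data).
#'
#' @return Named list of [tracer_spec()] objects
#'   (`"O15-water"`, `"F18-fallypride"`).
#' @examples
#' tr <- tracer("O15-water")
#' tr$arterial
#' @export
tracer_library <- function() {
  list(
    `O15-water` = tracer_spec(
      "O15-water", half_life = 122.24, injected_activity_mbq = 1000,
      arterial = aif_params(9.248, 1.535e3, 1.959e5, 2.061,
                            -3.902e-2, -8.271e-5),
      venous = aif_params(2.606, -4.458e2, 1.810e5, 2.060,
                          -3.902e-2, -8.271e-4),
      venous_delay = 5
    ),
    `F18-fallypride` = tracer_spec(
      "F18-fallypride", half_life = 6586.2, injected_activity_mbq = 250,
      arterial = aif_params(2.956, -4.907e2, 6.088e4, 2.059,
                            -3.902e-2, -8.271e-5),
      venous = aif_params(1.291e-1, -2.209e1, 1.197e4, 2.060,
                          -3.902e-2, -8.271e-4),
      venous_delay = 5
    )
  )
}

#' @rdname tracer_library
#' @param name Tracer name as listed by [tracer_library()].
#' @export
tracer <- function(name) {
  lib <- tracer_library()
  if (!name %in% names(lib)) {
    stop(sprintf("unknown tracer '%s'; shipped: %s", name,
                 paste(names(lib), collapse = ", ")), call. = FALSE)
  }
  lib[[name]]
}

#' Physical decay of a source
#'
#' @param a0 Activity at time zero, Bq.
#' @param t Elapsed time, s (non-negative).
#' @param half_life Half-life, s.
#' @return `a0 * 2^(-t / half_life)`, Bq.
#' @export
decayed_activity <- function(a0, t, half_life) {
  stopifnot(is.numeric(a0), all(a0 >= 0), is.numeric(t))
  .assert_scalar_num(half_life, "half_life", lower = 0, allow_zero = FALSE)
  if (any(t < 0)) stop("negative time", call. = FALSE)
  a0 * 2^(-t / half_life)
}

#' Tabulate an input-function curve
#'
#' @param params An [aif_params()] object.
#' @param step Time step, s.
#' @param horizon Last tabulated time, s.
#' @param delay Optional time shift, s (the curve is evaluated at
#'   `t - delay`; used for venous curves).
#' @return A tibble of class `aif_curve` with columns `time_s` and
#'   `concentration` (unit in `attr(, "unit")`).
#' @export
aif_curve <- function(params, step = 1, horizon = 300, delay = 0) {
  .assert_scalar_num(step, "step", lower = 0, allow_zero = FALSE)
  t <- seq(0, horizon, by = step)
  # times before `delay` map to non-positive model times, where the curve is 0
  out <- tibble(time_s = t,
                concentration = aif_value(params, pmax(0, t - delay)))
  attr(out, "unit") <- params$unit
  class(out) <- c("aif_curve", class(out))
  out
}

#' Export an input-function curve to CSV
#'
#' Writes a two-column CSV (`time_s`, `concentration_<unit>`) at full float
#' precision, re-readable with [readr::read_csv()].
#'
#' @inheritParams aif_curve
#' @param path Output file path.
#' @return Invisibly, the exported tibble.
#' @export
export_curve <- function(params, path, step = 1, horizon = 300, delay = 0) {
  cur <- aif_curve(params, step = step, horizon = horizon, delay = delay)
  unit_tag <- gsub("/", "_per_", attr(cur, "unit"))
  out <- tibble(time_s = cur$time_s)
  out[[paste0("concentration_", unit_tag)]] <- cur$concentration
  readr::write_csv(out, path)
  invisible(out)
}

#' Fit the linear-exponential model to sampled curve data
#'
#' Least-squares fit of the six free parameters (`a`, `b`, `c1`, `c2`,
#' `d1`, `d2`) by Levenberg-Marquardt; the breakpoints are re-solved from
#' the parameters at every step, so continuity at `t1` is enforced by
#' construction.  Reports the coefficient of determination r^2.
#'
#' @param samples Data frame with columns `time_s` and `concentration`
#'   (at least 8 rows spanning ramp and tail).
#' @param init Named list or vector of starting values for
#'   `a`, `b`, `c1`, `c2`, `d1`, `d2`.
#' @param horizon Breakpoint search horizon, s.
#' @return An object of class `aif_fit` with elements `params`
#'   ([aif_params()]), `r_squared`, `fitted`, `data`.  [tidy()] and
#'   [glance()] methods are provided.
#' @export
fit_aif <- function(samples, init, horizon = 600) {
  stopifnot(is.data.frame(samples),
            all(c("time_s", "concentration") %in% names(samples)))
  if (nrow(samples) < 8L) stop("need at least 8 samples", call. = FALSE)
  if (sd(samples$concentration) == 0) {
    stop("degenerate fit: samples are constant", call. = FALSE)
  }
  init <- as.list(init)
  stopifnot(all(c("a", "b", "c1", "c2", "d1", "d2") %in% names(init)))
  model_fun <- function(par, t) {
    p <- tryCatch(
      aif_params(par[["a"]], par[["b"]], par[["c1"]], par[["c2"]],
                 par[["d1"]], par[["d2"]], horizon = horizon),
      error = function(e) NULL
    )
    if (is.null(p)) {
      # no ramp/tail intersection in range: treat the whole range as ramp
      p <- aif_params(par[["a"]], par[["b"]], par[["c1"]], par[["c2"]],
                      par[["d1"]], par[["d2"]],
                      t0 = max(0, -par[["b"]] / par[["a"]]),
                      t1 = horizon + 1)
    }
    aif_value(p, t)
  }
  par0 <- unlist(init[c("a", "b", "c1", "c2", "d1", "d2")])
  # refine the starting point from the data: a linear fit to the rising
  # limb pins the ramp (and hence t0), and a log-linear fit to the early
  # tail pins the fast exponential.  Without this, a misplaced ramp onset
  # leaves the optimiser in a local minimum (the flat-zero lead-in of
  # late-arriving curves dominates the residuals).
  tt <- samples$time_s; yy <- samples$concentration
  i_pk <- which.max(yy); y_pk <- yy[i_pk]
  ramp_sel <- tt <= tt[i_pk] & yy > 0.2 * y_pk
  if (sum(ramp_sel) >= 3) {
    rf <- coef(lm(yy[ramp_sel] ~ tt[ramp_sel]))
    if (is.finite(rf[2]) && rf[2] > 0) {
      par0[["a"]] <- unname(rf[2]); par0[["b"]] <- unname(rf[1])
    }
  }
  slow <- par0[["c2"]] * exp(par0[["d2"]] * tt)
  tail_sel <- tt >= tt[i_pk] & (yy - slow) > pmax(0.02 * y_pk, 0)
  if (sum(tail_sel) >= 3) {
    tf <- coef(lm(log(yy[tail_sel] - slow[tail_sel]) ~ tt[tail_sel]))
    if (is.finite(tf[2]) && tf[2] < 0) {
      par0[["c1"]] <- unname(exp(tf[1])); par0[["d1"]] <- unname(tf[2])
    }
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000,
                                     ftol = 1e-13, ptol = 1e-13)
  # Levenberg-Marquardt in units of the current estimate (the natural
  # parameters span ~10 orders of magnitude), in two stages: the dominant
  # ramp/fast-tail parameters first with the small slow component frozen,
  # then all six.  A joint fit from a perturbed start tends to fall into a
  # local minimum that misuses (c2, d2) to mop up the c1 mismatch.
  lm_stage <- function(par, free) {
    sc <- pmax(abs(par), 1e-12)
    fit <- minpack.lm::nls.lm(
      par = par[free] / sc[free],
      fn = function(q) {
        par[free] <- q * sc[free]
        model_fun(par, samples$time_s) - samples$concentration
      },
      control = ctrl
    )
    par[free] <- fit$par * sc[free]
    list(par = par, fit = fit)
  }
  s1 <- lm_stage(par0, c("a", "b", "c1", "d1"))
  s2 <- lm_stage(s1$par, c("a", "b", "c1", "c2", "d1", "d2"))
  fit <- s2$fit
  est <- as.list(s2$par)
  params <- aif_params(est$a, est$b, est$c1, est$c2, est$d1, est$d2,
                       horizon = horizon)
  fitted_v <- aif_value(params, samples$time_s)
  ss_res <- sum((samples$concentration - fitted_v)^2)
  ss_tot <- sum((samples$concentration - mean(samples$concentration))^2)
  structure(
    list(params = params, r_squared = 1 - ss_res / ss_tot,
         fitted = fitted_v, data = as_tibble(samples), lm_fit = fit),
    class = "aif_fit"
  )
}

#' @export
print.aif_fit <- function(x, ...) {
  cat(sprintf("<aif_fit> r^2 = %.4f\n", x$r_squared))
  print(x$params)
  invisible(x)
}
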