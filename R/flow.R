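#' Vessel velocity waveforms
#'
#' Blood moves through each vessel as a 1-D plug flow with a prescribed
#' velocity waveform.  `uniform_flow()` gives constant velocity;
#' `pulsatile_flow()` gives a parametric single-beat profile
#' `v(phase) = v_dia + (v_sys - v_dia) * max(0, sin(pi * phase / width))^2`
#' repeated at the heart period (default 1 s, i.e. 60 bpm).  The pulsatile
#' profile is tabulated over one period; displacement integrals use
#' trapezoidal quadrature on the table.
#'
#' @param v Constant velocity, cm/s.
#' @return An object of class `velocity_waveform` with fields `kind`,
#'   `mean` (cm/s) and `period` (s).
#' @examples
#' displacement(uniform_flow(15), 1)    # 15 cm
#' w <- pulsatile_flow()
#' displacement(w, 2) / (2 * w$mean)    # ~1 after whole beats
#' @export
uniform_flow <- function(v = 15) {
  .assert_scalar_num(v, "v", lower = 0, allow_zero = FALSE)
  structure(list(kind = "uniform", mean = v, period = 1,
                 phase = c(0, 1), v = c(v, v)),
            class = "velocity_waveform")
}

#' @rdname uniform_flow
#' @param v_sys,v_dia Systolic and diastolic velocities, cm/s.
#' @param width Systolic fraction of the beat (dimensionless, in (0, 1]).
#' @param period Beat period, s (1 s = 60 bpm).
#' @param n Number of tabulation points per period.
#' @export
pulsatile_flow <- function(v_sys = 40, v_dia = 5, width = 0.35,
                           period = 1, n = 512L) {
  .assert_scalar_num(v_sys, "v_sys", lower = 0)
  .assert_scalar_num(v_dia, "v_dia", lower = 0)
  .assert_scalar_num(width, "width", lower = 0, upper = 1, allow_zero = FALSE)
  .assert_scalar_num(period, "period", lower = 0, allow_zero = FALSE)
  if (v_sys < v_dia) stop("v_sys must be >= v_dia", call. = FALSE)
  phase <- seq(0, 1, length.out = n + 1L)
  v <- v_dia + (v_sys - v_dia) *
    ifelse(phase < width, sin(pi * phase / width)^2, 0)
  velocity_waveform(kind = "pulsatile", period = period,
                    phase = phase, v = v)
}

#' @rdname uniform_flow
#' @param kind `"uniform"` or `"pulsatile"`.
#' @param phase,v_samples Tabulated phase grid on `[0, 1]` and velocities,
#'   cm/s, for a custom waveform.
#' @export
velocity_waveform <- function(kind = c("uniform", "pulsatile"), period = 1,
                              phase = NULL, v = NULL, v_samples = NULL) {
  kind <- match.arg(kind)
  v <- v %||% v_samples
  if (kind == "uniform") return(uniform_flow(mean(v)))
  stopifnot(is.numeric(phase), is.numeric(v), length(phase) == length(v))
  if (any(v < 0)) stop("waveform velocities must be non-negative",
                       call. = FALSE)
  # cumulative displacement over one period by trapezoid, cm
  dt <- diff(phase) * period
  cum <- c(0, cumsum((head(v, -1) + tail(v, -1)) / 2 * dt))
  structure(list(kind = kind, mean = cum[length(cum)] / period,
                 period = period, phase = phase, v = v, cum = cum),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("<velocity_waveform> %s: mean %.3g cm/s, period %.3g s\n",
              x$kind, x$mean, x$period))
  invisible(x)
}

#' Plug-flow displacement since time zero
#'
#' Integral of the velocity waveform from 0 to `t`: closed form for uniform
#' flow, trapezoidal quadrature over the tabulated beat otherwise.  Strictly
#' non-decreasing in `t`.
#'
#' @param waveform A [velocity_waveform()].
#' @param t Times, s (non-negative).
#' @return Displacements, cm.
#' @export
displacement <- function(waveform, t) {
  stopifnot(inherits(waveform, "velocity_waveform"), is.numeric(t))
  if (any(t < 0)) stop("negative time", call. = FALSE)
  if (waveform$kind == "uniform") return(waveform$mean * t)
  per <- waveform$period
  disp_per <- waveform$cum[length(waveform$cum)]
  nb <- floor(t / per)
  rem <- t - nb * per
  within <- approx(waveform$phase * per, waveform$cum, xout = rem,
                   rule = 2)$y
  nb * disp_per + within
}

#' Emission time of the fluid parcel now at distance x from the inlet
#'
#' Solves `displacement(t) - displacement(tau) = x` for the Lagrangian
#' emission time `tau <= t` by monotone bisection.  Returns `NA` where the
#' bolus front has not yet reached `x` (`displacement(t) < x`).
#'
#' @param waveform A [velocity_waveform()].
#' @param x Distances from the inlet, cm (non-negative).
#' @param t Observation times, s.
#' @param tol Bisection tolerance on the defining equation, cm.
#' @return Emission times, s, with `NA` before front arrival.
#' @export
retarded_time <- function(waveform, x, t, tol = 1e-9) {
  stopifnot(is.numeric(x), is.numeric(t))
  if (any(x < 0)) stop("negative distance", call. = FALSE)
  n <- max(length(x), length(t))
  x <- rep_len(x, n); t <- rep_len(t, n)
  if (waveform$kind == "uniform") {
    tau <- t - x / waveform$mean
    tau[tau < 0] <- NA_real_
    return(tau)
  }
  dt_ <- displacement(waveform, t)
  out <- rep(NA_real_, n)
  live <- which(dt_ >= x)
  if (length(live) == 0L) return(out)
  lo <- numeric(length(live)); hi <- t[live]
  target <- dt_[live] - x[live]          # displacement(tau) must equal this
  for (i in seq_len(64L)) {
    mid <- (lo + hi) / 2
    dm <- displacement(waveform, mid)
    up <- dm <= target
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
    if (max(hi - lo) * max(waveform$v) < tol) break
  }
  out[live] <- (lo + hi) / 2
  out
}

#' Attach an inlet curve and waveform to a vessel
#'
#' @param vessel A [cylinder_volume()] with role `"artery"` or `"vein"`.
#' @param inlet An [aif_params()] inlet concentration curve.
#' @param waveform A [velocity_waveform()].
#' @param direction `"+Z"` (arteries) or `"-Z"` (veins); the inlet sits at
#'   the upstream end of the vessel.
#' @param delay Time shift of the inlet curve, s (venous return delay).
#' @return An object of class `vessel_flow`.
#' @export
vessel_flow <- function(vessel, inlet, waveform,
                        direction = c("+Z", "-Z"), delay = 0) {
  direction <- match.arg(direction)
  stopifnot(inherits(vessel, "cylinder_volume"),
            inherits(inlet, "aif_params"),
            inherits(waveform, "velocity_waveform"))
  if (vessel$role == "artery" && direction != "+Z") {
    stop("arteries flow in +Z", call. = FALSE)
  }
  if (vessel$role == "vein" && direction != "-Z") {
    stop("veins flow in -Z", call. = FALSE)
  }
  .assert_scalar_num(delay, "delay", lower = 0)
  inlet_z <- if (direction == "+Z") -vessel$length / 2 else vessel$length / 2
  structure(list(vessel = vessel, inlet = inlet, waveform = waveform,
                 direction = direction, delay = delay, inlet_z = inlet_z),
            class = "vessel_flow")
}

#' Concentration at an axial position and time
#'
#' Plug-flow advection: the concentration at distance `x` from the inlet at
#' time `t` is the inlet curve evaluated at the retarded emission time;
#' zero before the bolus front arrives.
#'
#' @param flow A [vessel_flow()].
#' @param z Axial positions, cm (must lie within the vessel).
#' @param t Times, s.
#' @return Concentrations in the inlet curve's unit.
#' @export
concentration_at <- function(flow, z, t) {
  stopifnot(inherits(flow, "vessel_flow"))
  n <- max(length(z), length(t))
  z <- rep_len(z, n); t <- rep_len(t, n)
  half <- flow$vessel$length / 2
  if (any(z < -half - 1e-9 | z > half + 1e-9)) {
    stop("z outside the vessel", call. = FALSE)
  }
  x <- if (flow$direction == "+Z") z - flow$inlet_z else flow$inlet_z - z
  tau <- retarded_time(flow$waveform, x, t)
  conc <- numeric(n)
  ok <- !is.na(tau)
  # parcels emitted before `delay` carry the curve's value at t <= 0, i.e. 0
  conc[ok] <- aif_value(flow$inlet, pmax(0, tau[ok] - flow$delay))
  conc
}

#' Discretise vessel flows into a per-segment activity timeline
#'
#' Splits each vessel into axial segments and each time bin into rows of a
#' source table giving the activity (Bq) of every (segment, bin) pair, with
#' the concentration sampled at the segment midpoint and bin midpoint.
#' This is the source term consumed by the event engine.
#'
#' @param flows List of [vessel_flow()] objects.
#' @param horizon Simulated time span, s.
#' @param time_step Time bin width, s.
#' @param segment_length Axial segment length, cm.
#' @param scale History scaling factor in (0, 1]: activities are multiplied
#'   by `scale` so desk-scale runs sample proportionally fewer decays.
#' @return A timeline tibble with columns `source`, `x`, `y`, `radius`,
#'   `z_lo`, `z_hi`, `t_lo`, `t_hi`, `activity` (Bq).
#' @export
activity_timeline <- function(flows, horizon, time_step = 0.1,
                              segment_length = 0.5, scale = 1) {
  .assert_scalar_num(time_step, "time_step", lower = 0, allow_zero = FALSE)
  .assert_scalar_num(segment_length, "segment_length", lower = 0,
                     allow_zero = FALSE)
  .assert_scalar_num(scale, "scale", lower = 0, upper = 1, allow_zero = FALSE)
  if (time_step > horizon) stop("time_step larger than horizon", call. = FALSE)
  if (inherits(flows, "vessel_flow")) flows <- list(flows)
  bin_lo <- seq(0, horizon - time_step, by = time_step)
  t_mid <- bin_lo + time_step / 2
  out <- lapply(flows, function(fl) {
    v <- fl$vessel
    n_seg <- max(1L, ceiling(v$length / segment_length))
    edges <- seq(-v$length / 2, v$length / 2, length.out = n_seg + 1L)
    z_mid <- (head(edges, -1) + tail(edges, -1)) / 2
    seg_vol_ml <- pi * v$radius^2 * diff(edges)   # cm^3 == ml
    grid_z <- rep(z_mid, times = length(t_mid))
    grid_t <- rep(t_mid, each = n_seg)
    conc <- concentration_at(fl, grid_z, grid_t)
    to_bq <- if (fl$inlet$unit == "kBq/ml") 1000 else 1
    tibble(
      source = v$label,
      segment = rep(seq_len(n_seg), times = length(t_mid)),
      x = v$center[1], y = v$center[2], radius = v$radius,
      z_lo = rep(head(edges, -1), times = length(t_mid)),
      z_hi = rep(tail(edges, -1), times = length(t_mid)),
      t_lo = rep(bin_lo, each = n_seg),
      t_hi = rep(bin_lo + time_step, each = n_seg),
      activity = conc * to_bq * rep(seg_vol_ml, times = length(t_mid)) * scale
    )
  })
  bind_rows(out)
}

#' Build the BTAC source timeline for a phantom
#'
#' Convenience wrapper: attaches the tracer's arterial curve to every artery
#' (flowing +Z) and, optionally, the delayed venous curve to every vein
#' (flowing -Z), then discretises with [activity_timeline()].
#'
#' @param phantom A [phantom_model()] containing artery/vein volumes.
#' @param tracer A [tracer_spec()].
#' @param components Which vessel classes to include:
#'   `c("arterial", "venous")` or a subset.
#' @param arterial_waveform,venous_waveform [velocity_waveform()] objects;
#'   defaults: pulsatile arteries, uniform 5 cm/s veins.
#' @inheritParams activity_timeline
#' @return A timeline tibble (see [activity_timeline()]).
#' @export
btac_timeline <- function(phantom, tracer,
                          components = c("arterial", "venous"),
                          horizon = 150, time_step = 0.1,
                          segment_length = 0.5, scale = 1,
                          arterial_waveform = pulsatile_flow(),
                          venous_waveform = uniform_flow(5)) {
  stopifnot(inherits(phantom, "phantom_model"),
            inherits(tracer, "tracer_spec"))
  components <- match.arg(components, several.ok = TRUE)
  roles <- vapply(phantom$volumes, `[[`, character(1), "role")
  flows <- list()
  if ("arterial" %in% components) {
    flows <- c(flows, lapply(phantom$volumes[roles == "artery"], function(v) {
      vessel_flow(v, tracer$arterial, arterial_waveform, "+Z", delay = 0)
    }))
  }
  if ("venous" %in% components) {
    flows <- c(flows, lapply(phantom$volumes[roles == "vein"], function(v) {
      vessel_flow(v, tracer$venous, venous_waveform, "-Z",
                  delay = tracer$venous_delay)
    }))
  }
  if (length(flows) == 0L) stop("no matching vessels in the phantom",
                                call. = FALSE)
  activity_timeline(flows, horizon = horizon, time_step = time_step,
                    segment_length = segment_length, scale = scale)
}

#' Build a decaying point-source timeline
#'
#' Represents the decaying-source count-rate experiment: a small source
#' (default 1 mm^3, modelled as an equal-volume cylinder) whose activity
#' follows [decayed_activity()], sampled over a schedule of short
#' acquisition windows.  Window start times are evenly spaced over
#' `n_half_lives` half-lives, so window activities are log-spaced; each
#' window's simulated duration is chosen to give about
#' `histories_per_window` expected decays at the full (unscaled) activity,
#' which keeps randoms and deadtime behaviour faithful to the instantaneous
#' rate.
#'
#' @param position Length-3 numeric (x, y, z), cm.
#' @param a0 Start activity, Bq.
#' @param half_life Half-life, s.
#' @param n_windows Number of acquisition windows.
#' @param n_half_lives Schedule span in half-lives.
#' @param histories_per_window Target expected decays per window.
#' @param volume_mm3 Source volume, mm^3.
#' @return Timeline tibble with one row per window plus attribute
#'   `windows` (tibble of `t_lo`, `t_hi`, `duration`, `activity`).
#' @export
point_source_timeline <- function(position, a0, half_life,
                                  n_windows = 20, n_half_lives = 5,
                                  histories_per_window = 1e5,
                                  volume_mm3 = 1) {
  stopifnot(is.numeric(position), length(position) == 3L)
  .assert_scalar_num(a0, "a0", lower = 0, allow_zero = FALSE)
  t_start <- seq(0, n_half_lives * half_life, length.out = n_windows)
  act <- decayed_activity(a0, t_start, half_life)
  dur <- histories_per_window / act
  gap <- diff(c(t_start, n_half_lives * half_life + 1))
  dur <- pmin(dur, gap)                      # never overlap the next window
  height_cm <- 0.1
  radius_cm <- sqrt((volume_mm3 / 1000) / (pi * height_cm))
  out <- tibble(
    source = "point_source",
    segment = seq_len(n_windows),
    x = position[1], y = position[2], radius = radius_cm,
    z_lo = position[3] - height_cm / 2, z_hi = position[3] + height_cm / 2,
    t_lo = t_start, t_hi = t_start + dur,
    activity = act
  )
  attr(out, "windows") <- tibble(window = seq_len(n_windows), t_lo = t_start,
                                 t_hi = t_start + dur, duration = dur,
                                 activity = act)
  out
}
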