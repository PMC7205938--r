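#' Scintillator crystal materials
#'
#' `crystal_library()` ships the five scintillators considered for the
#' detector, with the physics constants the digitizer model uses (density,
#' decay time, energy resolution at 511 keV, attenuation length at 511 keV,
#' coincidence window) plus descriptive metadata (effective atomic number,
#' emission wavelength, light output, refractive index) that is stored but
#' not used by the simplified physics.
#'
#' @return `crystal_library()`: named list of `crystal_material` objects
#'   (`GSO`, `LSO`, `BGO`, `CeBr3`, `LaBr3`).
#' @examples
#' crystal("BGO")$attenuation_length_511_mm
#' @export
crystal_library <- function() {
  mk <- crystal_material
  list(
    GSO = mk("GSO", density = 6.71, decay_time_ns = 60,
             energy_resolution_pct = 8.5, attenuation_length_511_mm = 14.3,
             coincidence_window_ns = 4.5,
             metadata = list(z_eff = 58.6, wavelength_nm = 430,
                             light_output_ph_per_kev = "12-15",
                             refractive_index = 1.85)),
    LSO = mk("LSO", density = 7.40, decay_time_ns = 40,
             energy_resolution_pct = 10.0, attenuation_length_511_mm = 11.4,
             coincidence_window_ns = 4.5,
             metadata = list(z_eff = 65.0, wavelength_nm = 420,
                             light_output_ph_per_kev = "20-30",
                             refractive_index = 1.82)),
    BGO = mk("BGO", density = 7.13, decay_time_ns = 300,
             energy_resolution_pct = 10.2, attenuation_length_511_mm = 10.4,
             coincidence_window_ns = 10.0,
             metadata = list(z_eff = 74.2, wavelength_nm = 480,
                             light_output_ph_per_kev = "8",
                             refractive_index = 2.15)),
    CeBr3 = mk("CeBr3", density = 5.20, decay_time_ns = 17,
               energy_resolution_pct = 5.2, attenuation_length_511_mm = 19.6,
               coincidence_window_ns = 4.5,
               metadata = list(z_eff = 45.9, wavelength_nm = 370,
                               light_output_ph_per_kev = "60",
                               refractive_index = 1.88)),
    LaBr3 = mk("LaBr3", density = 5.30, decay_time_ns = 26,
               energy_resolution_pct = 3.2, attenuation_length_511_mm = 24.0,
               coincidence_window_ns = 4.5,
               metadata = list(z_eff = 46.9, wavelength_nm = 370,
                               light_output_ph_per_kev = "70",
                               refractive_index = 1.88))
  )
}

#' @rdname crystal_library
#' @param name Crystal name as listed by `crystal_library()`, or a
#'   `crystal_material` object (returned unchanged).
#' @export
crystal <- function(name) {
  if (inherits(name, "crystal_material")) return(name)
  lib <- crystal_library()
  if (!name %in% names(lib)) {
    stop(sprintf("unknown crystal '%s'; shipped: %s", name,
                 paste(names(lib), collapse = ", ")), call. = FALSE)
  }
  lib[[name]]
}

#' @rdname crystal_library
#' @param density Crystal density, g/cm^3.
#' @param decay_time_ns Scintillation decay time, ns.
#' @param energy_resolution_pct Energy resolution at 511 keV, percent FWHM.
#' @param attenuation_length_511_mm Attenuation length at 511 keV, mm.
#' @param coincidence_window_ns Coincidence window used with this crystal, ns.
#' @param metadata Free-form list of descriptive properties (unused).
#' @export
crystal_material <- function(name, density, decay_time_ns,
                             energy_resolution_pct,
                             attenuation_length_511_mm,
                             coincidence_window_ns, metadata = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  for (nm in c("density", "decay_time_ns",
               "attenuation_length_511_mm", "coincidence_window_ns")) {
    .assert_scalar_num(get(nm), nm, lower = 0, allow_zero = FALSE)
  }
  # zero resolution (ideal crystal) is allowed for testing
  .assert_scalar_num(energy_resolution_pct, "energy_resolution_pct",
                     lower = 0)
  structure(list(name = name, density = density,
                 decay_time_ns = decay_time_ns,
                 energy_resolution_pct = energy_resolution_pct,
                 attenuation_length_511_mm = attenuation_length_511_mm,
                 coincidence_window_ns = coincidence_window_ns,
                 metadata = metadata),
            class = "crystal_material")
}

#' @export
print.crystal_material <- function(x, ...) {
  cat(sprintf("<crystal_material> %s: lambda(511) %.3g mm, resolution %.3g%%, decay %.3g ns, window %.3g ns\n",
              x$name, x$attenuation_length_511_mm, x$energy_resolution_pct,
              x$decay_time_ns, x$coincidence_window_ns))
  invisible(x)
}

# block azimuths: 14 positions, indices increasing clockwise seen from +Z.
# Block 1 spans the top of the ring (the +Y axis is its trailing edge), so
# the retained volar subset 4-11 is symmetric about -Y and includes the two
# horizontal-equator blocks at 0 and 180 degrees.
.block_azimuth_deg <- function(k, n_per_ring = 14L) {
  90 - (k - 0.5) * 360 / n_per_ring
}

.make_blocks <- function(indices, ring_inner_radius, ring_z, material) {
  dims <- c(tangential = 2.45, axial = 3.0, radial = 2.0)
  r_c <- ring_inner_radius + dims[["radial"]] / 2
  grid <- expand.grid(idx = indices, ring = seq_along(ring_z))
  az <- .block_azimuth_deg(grid$idx)
  a <- az * pi / 180
  tibble(
    id = seq_len(nrow(grid)),
    ring_index = grid$ring,
    azimuth_index = grid$idx,
    azimuth_deg = az,
    cx = r_c * cos(a), cy = r_c * sin(a), cz = ring_z[grid$ring],
    nx = -cos(a), ny = -sin(a), nz = 0
  )
}

.scanner_config <- function(name, blocks, material, ring_inner_diameter,
                            n_axial_rings, energy_window, deadtime_factor,
                            timing_jitter_ns) {
  structure(list(
    name = name, blocks = blocks, material = material,
    ring_inner_diameter = ring_inner_diameter,
    n_axial_rings = n_axial_rings,
    energy_window = energy_window,
    coincidence_window_ns = material$coincidence_window_ns,
    deadtime_ns = deadtime_factor * material$decay_time_ns,
    timing_jitter_ns = timing_jitter_ns,
    block_dims = c(tangential = 2.45, axial = 3.0, radial = 2.0),
    axial_fov = 3.0 * n_axial_rings
  ), class = "scanner_config")
}

#' Build the closed-ring 14-detector scanner
#'
#' Fourteen monolithic scintillator blocks (2.45 x 3.0 x 2.0 cm^3,
#' tangential x axial x radial) in a single ring with a 3-cm axial field of
#' view, inner faces tangent to the ring circle.  Indices increase
#' clockwise viewed from +Z with block 1 spanning the top of the ring, so
#' blocks 4-11 form the volar arc (symmetric about -Y, including the two
#' horizontal blocks).
#'
#' @param material A crystal name or [crystal_material()] (default BGO).
#' @param ring_inner_diameter Inner ring diameter, cm.  The default 11 cm
#'   is the smallest round value that fits 14 blocks of 2.45 cm tangential
#'   width (>= 10.92 cm) around a human wrist.
#' @param energy_window Acceptance window `(low, high)` in keV, closed on
#'   both ends.
#' @param deadtime_factor Non-paralyzable per-block deadtime as a multiple
#'   of the crystal decay time.
#' @param timing_jitter_ns Gaussian timing jitter per single, ns (1 sigma).
#' @return An object of class `scanner_config`.
#' @examples
#' sc <- build_wristpet1()
#' nrow(sc$blocks)  # 14
#' @export
build_wristpet1 <- function(material = "BGO", ring_inner_diameter = 11,
                            energy_window = c(350, 650),
                            deadtime_factor = 3, timing_jitter_ns = 1) {
  material <- crystal(material)
  blocks <- .make_blocks(1:14, ring_inner_diameter / 2, 0, material)
  .scanner_config("wristPET1", blocks, material, ring_inner_diameter,
                  1L, energy_window, deadtime_factor, timing_jitter_ns)
}

#' Build the open half-ring scanner with 1-4 axial rings
#'
#' Keeps only the eight volar blocks (positions 4-11 of the closed ring);
#' `n_rings` identical half-rings are stacked axially at 3.0 cm pitch,
#' centred on z = 0, giving an axial field of view of `3 * n_rings` cm.
#' Coincidences are allowed between any two blocks, including across rings.
#'
#' @inheritParams build_wristpet1
#' @param n_rings Number of axial rings, 1 to 4.
#' @return An object of class `scanner_config`.
#' @examples
#' nrow(build_wristpet2(n_rings = 4)$blocks)  # 32
#' @export
build_wristpet2 <- function(material = "BGO", n_rings = 1,
                            ring_inner_diameter = 11,
                            energy_window = c(350, 650),
                            deadtime_factor = 3, timing_jitter_ns = 1) {
  if (!is.numeric(n_rings) || length(n_rings) != 1L ||
      n_rings != round(n_rings) || n_rings < 1 || n_rings > 4) {
    stop("n_rings must be an integer in 1..4", call. = FALSE)
  }
  n_rings <- as.integer(n_rings)
  material <- crystal(material)
  ring_z <- (seq_len(n_rings) - (n_rings + 1) / 2) * 3.0
  blocks <- .make_blocks(4:11, ring_inner_diameter / 2, ring_z, material)
  .scanner_config("wristPET2", blocks, material, ring_inner_diameter,
                  n_rings, energy_window, deadtime_factor, timing_jitter_ns)
}

#' @export
print.scanner_config <- function(x, ...) {
  cat(sprintf("<scanner_config> %s: %d %s blocks, %d ring(s), axial FoV %.1f cm, window [%g, %g] keV, tau %g ns, coincidence window %g ns\n",
              x$name, nrow(x$blocks), x$material$name, x$n_axial_rings,
              x$axial_fov, x$energy_window[1], x$energy_window[2],
              x$deadtime_ns, x$coincidence_window_ns))
  invisible(x)
}

#' @export
as_tibble.scanner_config <- function(x, ...) x$blocks

#' Chord length of a ray inside a detector block
#'
#' @param block One row of `scanner$blocks` (or a list with fields `cx`,
#'   `cy`, `cz`, `azimuth_deg`).
#' @param origin,direction Length-3 numerics; direction normalised
#'   internally.
#' @param dims Block dimensions, cm (tangential, axial, radial).
#' @return Chord length in cm (0 on miss).
#' @export
crystal_pathlength <- function(block, origin, direction,
                               dims = c(tangential = 2.45, axial = 3.0,
                                        radial = 2.0)) {
  d <- .normalize3(direction)
  a <- block$azimuth_deg * pi / 180
  nrm <- c(-cos(a), -sin(a), 0)            # inward normal (radial axis)
  tng <- c(-sin(a), cos(a), 0)
  axl <- c(0, 0, 1)
  po <- origin - c(block$cx, block$cy, block$cz)
  lo <- c(sum(po * nrm), sum(po * tng), sum(po * axl))
  ld <- c(sum(d * nrm), sum(d * tng), sum(d * axl))
  half <- c(dims[["radial"]], dims[["tangential"]], dims[["axial"]]) / 2
  t1 <- -Inf; t2 <- Inf
  for (i in 1:3) {
    if (abs(ld[i]) < 1e-12) {
      if (abs(lo[i]) > half[i]) return(0)
    } else {
      ta <- (-half[i] - lo[i]) / ld[i]
      tb <- (half[i] - lo[i]) / ld[i]
      t1 <- max(t1, min(ta, tb)); t2 <- min(t2, max(ta, tb))
    }
  }
  tin <- max(t1, 0)
  if (t2 <= tin) return(0)
  t2 - tin
}

#' Per-photon interaction probability in a crystal
#'
#' `1 - exp(-pathlength / lambda)` with `lambda` the crystal's attenuation
#' length at 511 keV.  Any interaction counts as a detection; the full
#' incident energy is deposited.
#'
#' @param pathlength Chord lengths in the crystal, cm.
#' @param material A crystal name or [crystal_material()].
#' @return Detection probabilities.
#' @examples
#' detection_probability(2.0, "BGO")  # 1 - exp(-20/10.4)
#' @export
detection_probability <- function(pathlength, material) {
  material <- crystal(material)
  if (any(pathlength < 0)) stop("negative pathlength", call. = FALSE)
  1 - exp(-pathlength * 10 / material$attenuation_length_511_mm)
}

#' Gaussian energy blurring
#'
#' The deposited energy is blurred with a Gaussian whose FWHM scales as
#' `resolution * 511 keV * sqrt(511 / E)` (inverse-square-root energy
#' scaling of the fractional resolution quoted at 511 keV).  Negative draws
#' are clamped at 0.
#'
#' @param energy True deposited energies, keV (> 0).
#' @param material A crystal name or [crystal_material()].
#' @return Blurred energies, keV.
#' @export
blur_energy <- function(energy, material) {
  material <- crystal(material)
  if (any(energy <= 0)) stop("energy must be positive", call. = FALSE)
  res <- material$energy_resolution_pct / 100
  if (res == 0) return(energy)
  fwhm <- res * 511 * sqrt(511 / energy)
  pmax(0, rnorm(length(energy), mean = energy, sd = fwhm / 2.354820045))
}

#' Energy window acceptance
#'
#' @param energy Energies, keV.
#' @param window Length-2 numeric `(low, high)`, keV; the interval is
#'   closed at both ends.
#' @return Logical vector.
#' @export
apply_energy_window <- function(energy, window = c(350, 650)) {
  stopifnot(is.numeric(window), length(window) == 2L, window[1] < window[2])
  energy >= window[1] & energy <= window[2]
}

#' Non-paralyzable deadtime
#'
#' An accepted event at time `t` blocks every event in `(t, t + tau]`;
#' blocked events do not extend the dead period.  Applied independently per
#' detector block.
#'
#' @param times Event times for one block, s, sorted ascending.
#' @param tau Deadtime constant, s.
#' @return Logical vector: `TRUE` for surviving events.
#' @export
apply_deadtime <- function(times, tau) {
  .assert_scalar_num(tau, "tau", lower = 0)
  if (is.unsorted(times)) stop("event times must be sorted", call. = FALSE)
  n <- length(times)
  keep <- logical(n)
  if (n == 0L) return(keep)
  if (tau == 0) return(rep(TRUE, n))
  last <- -Inf
  for (i in seq_len(n)) {
    # the dead interval (last, last + tau] is open at `last`: a simultaneous
    # event is not blocked
    if (times[i] > last + tau || times[i] == last) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  keep
}
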