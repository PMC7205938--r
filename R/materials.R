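#' Define a photon-transport material
#'
#' A material is characterised, for the simplified 511-keV transport used
#' here, by its linear attenuation coefficient and the fraction of
#' interactions that are Compton scatters (the remainder are treated as
#' photoelectric absorption).
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3 (bookkeeping only; transport uses
#'   `mu_511` directly).
#' @param mu_511 Linear attenuation coefficient at 511 keV, 1/cm.
#' @param compton_fraction Fraction of interactions at 511 keV that are
#'   Compton scatters, in `[0, 1]`.
#' @return An object of class `pet_material`.
#' @examples
#' material("water", 1.0, 0.0958)
#' @export
material <- function(name, density, mu_511, compton_fraction = 0.99) {
  stopifnot(is.character(name), length(name) == 1L)
  .assert_scalar_num(density, "density", lower = 0, allow_zero = FALSE)
  .assert_scalar_num(mu_511, "mu_511", lower = 0, allow_zero = FALSE)
  .assert_scalar_num(compton_fraction, "compton_fraction", lower = 0, upper = 1)
  structure(
    list(name = name, density = density, mu_511 = mu_511,
         compton_fraction = compton_fraction),
    class = "pet_material"
  )
}

#' Default phantom materials
#'
#' Narrow-beam linear attenuation coefficients at 511 keV: water 0.0958/cm,
#' cortical bone 0.178/cm, whole blood 0.101/cm.  The Compton fraction at
#' 511 keV is effectively 1 for these low-Z media; 0.99 is used so a small
#' photoelectric channel remains.  The background outside the arm is air;
#' its attenuation (~1e-4/cm) is ignored by the transport step, which treats
#' everything outside the phantom volumes as vacuum.
#'
#' @param overrides Named list of per-material field overrides, e.g.
#'   `list(water = list(mu_511 = 0.096))`.
#' @return Named list of [material()] objects: `water`, `bone`, `blood`, `air`.
#' @export
default_materials <- function(overrides = NULL) {
  mats <- list(
    water = list(name = "water", density = 1.00, mu_511 = 0.0958,
                 compton_fraction = 0.99),
    bone  = list(name = "bone", density = 1.92, mu_511 = 0.178,
                 compton_fraction = 0.99),
    blood = list(name = "blood", density = 1.06, mu_511 = 0.101,
                 compton_fraction = 0.99),
    air   = list(name = "air", density = 0.0012, mu_511 = 1.04e-4,
                 compton_fraction = 0.99)
  )
  mats <- .deep_merge(mats, overrides)
  lapply(mats, function(m) {
    material(m$name, m$density, m$mu_511, m$compton_fraction)
  })
}

#' @export
print.pet_material <- function(x, ...) {
  cat(sprintf("<pet_material> %s: density %.4g g/cm^3, mu(511 keV) %.4g /cm, Compton fraction %.2f\n",
              x$name, x$density, x$mu_511, x$compton_fraction))
  invisible(x)
}
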