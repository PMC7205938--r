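test_that("the shipped crystal table carries the reference constants", {
  lib <- crystal_library()
  want <- list(
    #          density decay  res  att.len window
    GSO   = c(6.71,  60, 8.5, 14.3, 4.5),
    LSO   = c(7.40,  40, 10.0, 11.4, 4.5),
    BGO   = c(7.13, 300, 10.2, 10.4, 10.0),
    CeBr3 = c(5.20,  17, 5.2, 19.6, 4.5),
    LaBr3 = c(5.30,  26, 3.2, 24.0, 4.5)
  )
  for (nm in names(want)) {
    m <- lib[[nm]]
    expect_identical(
      c(m$density, m$decay_time_ns, m$energy_resolution_pct,
        m$attenuation_length_511_mm, m$coincidence_window_ns),
      want[[nm]], info = nm
    )
  }
  expect_error(crystal("NaI"), "unknown crystal")
})

test_that("wristPET1 has 14 equally spaced blocks on the ring circle", {
  sc <- build_wristpet1("BGO")
  bl <- sc$blocks
  expect_equal(nrow(bl), 14)
  pitch <- diff(sort(bl$azimuth_deg))
  expect_equal(pitch, rep(360 / 14, 13), tolerance = 1e-9)
  # centres at inner radius + half the radial depth
  expect_equal(sqrt(bl$cx^2 + bl$cy^2), rep(11 / 2 + 1, 14),
               tolerance = 1e-9)
  expect_equal(sc$axial_fov, 3)
  expect_equal(sc$coincidence_window_ns, 10)   # BGO
  expect_equal(sc$deadtime_ns, 3 * 300)
})

test_that("wristPET2 keeps the volar arc, stacked over 1-4 rings", {
  expect_equal(nrow(build_wristpet2(n_rings = 1)$blocks), 8)
  sc4 <- build_wristpet2(n_rings = 4)
  expect_equal(nrow(sc4$blocks), 32)
  expect_equal(sc4$axial_fov, 12)
  expect_equal(sort(unique(sc4$blocks$cz)), c(-4.5, -1.5, 1.5, 4.5))
  expect_error(build_wristpet2(n_rings = 5), "1..4")
  expect_error(build_wristpet2(n_rings = 0), "1..4")
  # the kept arc is the wristPET1 subset 4-11: a contiguous arc symmetric
  # about -Y that includes the two horizontal-equator blocks
  az <- sort(build_wristpet2(n_rings = 1)$blocks$azimuth_deg)
  expect_equal(az, seq(-180, 0, by = 360 / 14), tolerance = 1e-9)
  expect_true(all(build_wristpet2(n_rings = 1)$blocks$cy < 1e-9))
  reflected <- sort(-180 - az)
  expect_equal(az, reflected, tolerance = 1e-9)
  # same angular positions as wristPET1 blocks 4-11
  sc1 <- build_wristpet1()
  expect_setequal(round(az, 9),
                  round(sc1$blocks$azimuth_deg[sc1$blocks$id %in% 4:11], 9))
})

test_that("crystal_pathlength matches a dense ray-marching oracle", {
  sc <- build_wristpet1("BGO")
  # normal incidence through a block centre crosses the full radial depth
  b <- sc$blocks[3, ]
  a <- b$azimuth_deg * pi / 180
  expect_equal(crystal_pathlength(b, c(0, 0, 0), c(cos(a), sin(a), 0)),
               2.0, tolerance = 1e-9)
  # miss
  expect_equal(crystal_pathlength(b, c(0, 0, 0), c(-cos(a), -sin(a), 0)), 0)
  set.seed(405)
  worst <- 0
  for (i in seq_len(1000)) {
    b <- sc$blocks[sample(14, 1), ]
    origin <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, -2, 2))
    target <- c(b$cx, b$cy, b$cz) + runif(3, -1.4, 1.4)
    dir <- target - origin
    got <- crystal_pathlength(b, origin, dir)
    want <- oracle_block_chord(b, origin, dir, max_length = 12, step = 1e-3)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 0.01)
})

test_that("detection_probability follows the attenuation length", {
  bgo <- crystal("BGO")
  expect_equal(detection_probability(bgo$attenuation_length_511_mm / 10,
                                     bgo), 1 - exp(-1))
  expect_equal(detection_probability(2.0, "BGO"), 1 - exp(-20 / 10.4))
  expect_equal(detection_probability(2.0, "BGO"), 0.8539, tolerance = 1e-3)
  expect_equal(detection_probability(0, "BGO"), 0)
  expect_error(detection_probability(-1, "BGO"), "negative")
  # efficiency ordering follows inverse attenuation length
  p <- vapply(c("BGO", "LSO", "GSO", "CeBr3", "LaBr3"),
              function(m) detection_probability(2, m), numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("energy blurring is unbiased with the quoted FWHM at 511 keV", {
  ideal <- crystal_material("ideal", 7, 300, 0, 10.4, 10)
  expect_identical(blur_energy(rep(511, 5), ideal), rep(511, 5))
  set.seed(406)
  draws <- blur_energy(rep(511, 1e5), "BGO")
  expect_lt(abs(mean(draws) - 511), 0.5)
  fwhm <- sd(draws) * 2 * sqrt(2 * log(2))
  expect_equal(fwhm, 0.102 * 511, tolerance = 0.02)  # 52.12 keV
  expect_error(blur_energy(-1, "BGO"), "positive")
})

test_that("the energy window is closed at both ends", {
  expect_true(apply_energy_window(511))
  expect_false(apply_energy_window(170.33))    # 180-degree Compton photon
  expect_true(apply_energy_window(350))
  expect_true(apply_energy_window(650))
  expect_false(apply_energy_window(349.999))
  expect_error(apply_energy_window(500, c(650, 350)))
})

test_that("non-paralyzable deadtime blocks the (t, t+tau] interval", {
  expect_equal(apply_deadtime(c(0, 1, 2), 0), rep(TRUE, 3))
  expect_equal(apply_deadtime(c(0, 0.5, 1.1), 1), c(TRUE, FALSE, TRUE))
  expect_equal(apply_deadtime(c(0, 1, 2), 1), c(TRUE, FALSE, TRUE))
  expect_error(apply_deadtime(c(1, 0), 0.1), "sorted")
  # Poisson stream: surviving fraction ~ 1 / (1 + r * tau) at r * tau = 0.1
  set.seed(407)
  r <- 1e4
  times <- cumsum(rexp(1e5, rate = r))
  tau <- 0.1 / r
  surv <- mean(apply_deadtime(times, tau))
  expect_equal(surv, 1 / 1.1, tolerance = 0.02)
})
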