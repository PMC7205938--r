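test_that("decay sampling is Poisson with uniform positions and times", {
  # zero activity: no decays
  tl0 <- steady_source_timeline(0, 1)
  expect_equal(nrow(sample_decays(tl0)), 0)
  expect_error(sample_decays(dplyr::mutate(tl0, activity = -1)), "negative")
  # 1 MBq for 1 ms: counts have mean 1000 (checked over 100 repeats at 4 sigma)
  set.seed(408)
  counts <- replicate(100, nrow(sample_decays(
    steady_source_timeline(1e6, 1e-3))))
  expect_lt(abs(mean(counts) - 1000), 4 * sqrt(1000 / 100))
  # index of dispersion ~ 1 across 1e4 unit-mean bins
  tl <- steady_source_timeline(1e3, 10, n_windows = 1e4)
  d <- sample_decays(tl)
  per_bin <- tabulate(findInterval(d$time, tl$t_lo), nbins = nrow(tl))
  expect_equal(var(per_bin) / mean(per_bin), 1, tolerance = 0.05)
  # positions stay inside the source cylinder
  expect_true(all(d$x^2 + d$y^2 <= 0.05^2 + 1e-12))
  expect_true(all(abs(d$z) <= 0.05 + 1e-12))
})

test_that("annihilation photons are back-to-back 511 keV with isotropic emission", {
  set.seed(409)
  d <- sample_decays(steady_source_timeline(1e7, 1e-3))
  ph <- emit_annihilation(d)
  expect_equal(nrow(ph), 2 * nrow(d))
  expect_true(all(ph$energy == 511))
  p1 <- ph[ph$photon == 1, ]; p2 <- ph[ph$photon == 2, ]
  dots <- p1$dx * p2$dx + p1$dy * p2$dy + p1$dz * p2$dz
  expect_equal(dots, rep(-1, nrow(p1)), tolerance = 1e-12)
  # z-component uniform on [-1, 1]
  ks <- suppressWarnings(stats::ks.test(p1$dz[1:1e4], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("transport reproduces Beer-Lambert survival through water", {
  ph <- build_water_phantom()
  n <- 1e5
  set.seed(410)
  # full 8-cm diameter chord
  photons <- make_photons(n, c(0, -3.99999, 0), c(0, 1, 0))
  out <- transport_photon(photons, ph)
  p_surv <- mean(out$outcome == "escaped" & !out$scattered)
  want <- attenuation_factor(tibble::tibble(mu_511 = 0.0958,
                                            pathlength = 7.99999))
  expect_equal(p_surv, want, tolerance = 0.01)
  # scattered photons obey the Compton limit: none below 170.33 keV
  scat <- out$energy[out$scattered & out$outcome == "escaped"]
  expect_gt(length(scat), 100)
  expect_gte(min(scat), 511 / 3 - 1e-9)
  expect_true(all(scat < 511))
  # near-zero attenuation: everything escapes unscattered
  thin <- build_water_phantom(materials = list(water = list(mu_511 = 1e-9)))
  out2 <- transport_photon(make_photons(1e3, c(0, 0, 0), c(1, 0, 0)), thin)
  expect_true(all(out2$outcome == "escaped" & !out2$scattered))
})

test_that("detection tests the first block hit with the crystal efficiency", {
  sc <- build_wristpet1("BGO", timing_jitter_ns = 1)
  set.seed(411)
  # photon aimed away from every block
  miss <- make_photons(10, c(0, 0, 0), c(0, 0, 1))
  expect_equal(nrow(detect_photon(miss, sc)), 0)
  # normal incidence on one block: acceptance ~ (1 - exp(-2.0 cm / lambda))
  b <- sc$blocks[5, ]
  a <- b$azimuth_deg * pi / 180
  n <- 1e5
  hits <- detect_photon(make_photons(n, c(0, 0, 0), c(cos(a), sin(a), 0)), sc)
  expect_true(all(hits$block == b$id))
  expect_equal(nrow(hits) / n, detection_probability(2, "BGO"),
               tolerance = 0.02)
  # a 180-degree-scattered photon is rejected by the energy window in
  # >= 99% of draws (only the blur tail can pass)
  low <- detect_photon(make_photons(2e4, c(0, 0, 0), c(cos(a), sin(a), 0),
                                    energy = 170.33), sc)
  expect_lt(nrow(low) / 2e4, 0.01 * detection_probability(2, "BGO") + 0.005)
})

test_that("the coincidence sorter implements keep-if-all-are-good", {
  mk <- function(t, b) tibble::tibble(time = t, block = b,
                                      energy = 511,
                                      decay_id = seq_along(t),
                                      scattered = FALSE)
  w <- 10e-9
  # two singles half a window apart on different blocks
  expect_equal(nrow(sort_coincidences(mk(c(0, w / 2), c(1, 5)), w)), 1)
  # same pair on one block is discarded
  expect_equal(nrow(sort_coincidences(mk(c(0, w / 2), c(3, 3)), w)), 0)
  # two windows apart: no coincidence
  expect_equal(nrow(sort_coincidences(mk(c(0, 2 * w), c(1, 5)), w)), 0)
  # triple on three distinct blocks: all three pairs
  expect_equal(nrow(sort_coincidences(mk(c(0, w / 3, w / 2), c(1, 5, 9)),
                                      w)), 3)
  # triple with two on one block: the whole multiple is discarded
  expect_equal(nrow(sort_coincidences(mk(c(0, w / 3, w / 2), c(1, 5, 1)),
                                      w)), 0)
  expect_error(sort_coincidences(mk(c(1, 0), c(1, 2)), w), "sorted")
})

test_that("the sorter matches an exhaustive small-case oracle", {
  set.seed(412)
  w <- 1
  for (case in seq_len(200)) {
    n <- sample(2:8, 1)
    t <- sort(round(runif(n, 0, 4), 2))
    b <- sample(1:4, n, replace = TRUE)
    singles <- tibble::tibble(time = t, block = b, energy = 511,
                              decay_id = seq_len(n), scattered = FALSE)
    got <- sort_coincidences(singles, w)
    want <- oracle_sorter(t, b, w)
    expect_equal(nrow(got), length(want))
    if (nrow(got) > 0) {
      got_pairs <- lapply(seq_len(nrow(got)),
                          function(i) c(got$t1[i], got$t2[i]))
      expect_setequal(got_pairs, want)
    }
    # conservation: a single never appears in two different windows
    expect_lte(length(unique(c(got$decay_id1, got$decay_id2))),
               nrow(got) * 2)
  }
})

test_that("coincidences classify by decay identity and scatter flags", {
  co <- tibble::tibble(
    t1 = 0, t2 = 1e-9, block1 = 1, block2 = 2,
    decay_id1 = c(7, 7, 7, 3), decay_id2 = c(7, 7, 4, 9),
    scattered1 = c(FALSE, TRUE, FALSE, TRUE),
    scattered2 = c(FALSE, FALSE, FALSE, TRUE)
  )
  expect_equal(classify_coincidence(co)$class,
               c("true", "scattered", "random", "random"))
})

test_that("a toy two-block setup matches the closed-form coincidence rate", {
  # nearly transparent phantom, ideal timing: coincidence fraction =
  # geometric pair acceptance x per-photon detection probability^2
  thin <- build_water_phantom(materials = list(water = list(mu_511 = 1e-9)))
  sc <- build_wristpet1("BGO", deadtime_factor = 0, timing_jitter_ns = 0.1)
  two <- sc
  two$blocks <- sc$blocks[c(4, 11), ]   # opposed equator blocks
  set.seed(413)
  tl <- steady_source_timeline(5e6, 2e-2)
  sim <- simulate_run(tl, thin, two, seed = 414)
  n <- sim$n_decays
  # direction-only geometric acceptance for the pair, via an independent
  # direction sample and the chord primitive
  z <- runif(4e4, -1, 1); phi <- runif(4e4, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  dirs <- cbind(s * cos(phi), s * sin(phi), z)
  chord1 <- apply(dirs, 1, function(d)
    crystal_pathlength(two$blocks[1, ], c(0, 0, 0), d))
  chord2 <- apply(dirs, 1, function(d)
    crystal_pathlength(two$blocks[2, ], c(0, 0, 0), -d))
  both <- chord1 > 0 & chord2 > 0
  p_pair <- mean(
    detection_probability(chord1[both], "BGO") *
      detection_probability(chord2[both], "BGO")
  ) * mean(both)
  got <- nrow(sim$coincidences) / n
  expect_equal(got, p_pair, tolerance = 0.1)
})

test_that("simulation runs are reproducible with a fixed seed", {
  ph <- build_forearm_phantom()
  sc <- build_wristpet2("BGO", n_rings = 1)
  tr <- tracer("O15-water")
  tl <- btac_timeline(ph, tr, components = "arterial", horizon = 5,
                      time_step = 0.5, scale = 0.002)
  s1 <- simulate_run(tl, ph, sc, seed = 99)
  s2 <- simulate_run(tl, ph, sc, seed = 99)
  expect_identical(s1$singles, s2$singles)
  expect_identical(s1$coincidences, s2$coincidences)
  s3 <- simulate_run(tl, ph, sc, seed = 100)
  expect_false(identical(s1$singles, s3$singles))
  # every coincidence consumes two distinct singles, none reused
  key <- c(paste(s1$coincidences$t1, s1$coincidences$block1),
           paste(s1$coincidences$t2, s1$coincidences$block2))
  expect_equal(anyDuplicated(key), 0)
})
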