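shipped_curves <- function() {
  lib <- tracer_library()
  list(`15O arterial` = lib[["O15-water"]]$arterial,
       `15O venous` = lib[["O15-water"]]$venous,
       `18F arterial` = lib[["F18-fallypride"]]$arterial,
       `18F venous` = lib[["F18-fallypride"]]$venous)
}

test_that("solve_breakpoints finds the ramp zero crossing and intersection", {
  # linear ramp against a constant tail: t0 = 10, t1 = 30
  bp <- solve_breakpoints(list(a = 1, b = -10, c1 = 20, c2 = 0,
                               d1 = 0, d2 = 0))
  expect_equal(unname(bp["t0"]), 10)
  expect_equal(unname(bp["t1"]), 30, tolerance = 1e-8)
  # positive intercept clamps t0 at zero
  bp <- solve_breakpoints(list(a = 1, b = 5, c1 = 1e3, c2 = 0,
                               d1 = -0.01, d2 = 0))
  expect_equal(unname(bp["t0"]), 0)
  # 18F arterial ramp crosses zero at -b/a = 490.7 / 2.956
  f18 <- tracer("F18-fallypride")$arterial
  expect_equal(f18$t0, 165.99, tolerance = 1e-4)
  expect_error(
    solve_breakpoints(list(a = 1e-6, b = -10, c1 = 1e9, c2 = 0,
                           d1 = -1e-6, d2 = 0)),
    "no ramp/tail intersection"
  )
  expect_error(solve_breakpoints(list(a = 0, b = 1, c1 = 1, c2 = 0,
                                      d1 = 0, d2 = 0)),
               "non-zero")
})

test_that("aif_value is zero at t0, continuous at the solved t1, and decays", {
  for (nm in names(shipped_curves())) {
    p <- shipped_curves()[[nm]]
    peak <- aif_value(p, p$t1)
    expect_equal(aif_value(p, p$t0), 0, info = nm)
    # continuity at t1: ramp limit vs tail value
    eps <- 1e-9 * max(1, p$t1)
    gap <- abs(aif_value(p, p$t1) - (p$a * (p$t1 - eps) + p$b))
    expect_lt(gap, 1e-6 * peak)
    # non-negativity on a dense grid
    expect_gte(min(aif_value(p, seq(0, 600, by = 0.25))), 0)
  }
  # the 15O arterial tail decays to well below the peak (the other curves
  # carry a small slow component that keeps a low plateau)
  p <- tracer("O15-water")$arterial
  expect_lt(aif_value(p, 10 * p$t1), 1e-3 * aif_value(p, p$t1))
})

test_that("venous curves are delayed and dispersed versions of arterial", {
  for (tr in tracer_library()) {
    art_peak <- aif_value(tr$arterial, tr$arterial$t1)
    ven_peak <- aif_value(tr$venous, tr$venous$t1)
    expect_lt(ven_peak, art_peak)
    expect_gt(tr$venous$t1 + tr$venous_delay, tr$arterial$t1)
  }
})

test_that("decayed_activity follows the half-life law", {
  expect_equal(decayed_activity(3e6, 0, 100), 3e6)
  expect_equal(decayed_activity(3e6, 100, 100), 1.5e6)
  # 14 MBq of 18F after one half-life
  expect_equal(decayed_activity(14e6, 6586.2, 6586.2), 7e6)
  expect_error(decayed_activity(1e6, -1, 100), "negative")
})

test_that("curve export round-trips and respects the venous delay", {
  p <- tracer("O15-water")$arterial
  path <- withr::local_tempfile(fileext = ".csv")
  out <- export_curve(p, path, step = 1, horizon = 300)
  expect_equal(nrow(out), 301)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back[[2]], aif_value(p, back$time_s), tolerance = 1e-12)

  ven <- tracer("O15-water")$venous
  vcur <- aif_curve(ven, step = 1, horizon = 300, delay = 5)
  first_on <- ven$t0 + 5
  expect_true(all(vcur$concentration[vcur$time_s < first_on] == 0))
  expect_gt(max(vcur$concentration[vcur$time_s > first_on]), 0)
})

test_that("fit_aif recovers its own generator", {
  p <- tracer("O15-water")$arterial
  t <- seq(0, 300, by = 1)
  samples <- tibble::tibble(time_s = t, concentration = aif_value(p, t))
  init <- list(a = p$a * 1.15, b = p$b * 0.9, c1 = p$c1 * 1.1,
               c2 = p$c2 * 1.2, d1 = p$d1 * 0.9, d2 = p$d2 * 1.1)
  fit <- fit_aif(samples, init)
  expect_gte(fit$r_squared, 0.999)
  for (nm in c("a", "b", "c1", "c2", "d1", "d2")) {
    expect_equal(fit$params[[nm]], p[[nm]], tolerance = 0.01)
  }
})

test_that("fit_aif handles noisy samples and degenerate input", {
  set.seed(403)
  p <- tracer("F18-fallypride")$arterial
  t <- seq(0, 400, by = 1)
  clean <- aif_value(p, t)
  noisy <- clean * (1 + rnorm(length(t), sd = 0.01))
  init <- list(a = p$a * 1.1, b = p$b * 0.95, c1 = p$c1 * 1.05,
               c2 = p$c2, d1 = p$d1 * 1.05, d2 = p$d2)
  fit <- fit_aif(tibble::tibble(time_s = t, concentration = noisy), init)
  expect_gte(fit$r_squared, 0.98)
  # the ramp and fast tail parameters are identifiable at 1% noise; the
  # small slow component (c2, d2) contributes ~2 out of a ~50 kBq/ml peak
  # and is not
  for (nm in c("a", "b", "c1", "d1")) {
    expect_equal(fit$params[[nm]], p[[nm]], tolerance = 0.05)
  }
  expect_error(
    fit_aif(tibble::tibble(time_s = 1:20, concentration = 0), init),
    "degenerate"
  )
})

test_that("aif_fit tidiers expose parameters and fit quality", {
  p <- tracer("O15-water")$arterial
  t <- seq(0, 200, by = 2)
  fit <- fit_aif(tibble::tibble(time_s = t, concentration = aif_value(p, t)),
                 init = list(a = p$a, b = p$b, c1 = p$c1, c2 = p$c2,
                             d1 = p$d1, d2 = p$d2))
  td <- tidy(fit)
  expect_setequal(td$term, c("a", "b", "c1", "c2", "d1", "d2", "t0", "t1"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_gte(gl$r.squared, 0.999)
})
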