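# Small-scale end-to-end runs of the experiment drivers: structural
# checks, superposition and reproducibility.  The quantitative comparisons
# against the published ratios live in test-acceptance.R.

tiny_btac_config <- function() {
  cfg <- default_run_config("btac")
  cfg$tracer <- "F18-fallypride"
  cfg$scale <- 0.05
  cfg$sim$horizon <- 300
  cfg$sim$time_step <- 0.2
  cfg$seed <- 21L
  cfg
}

test_that("the BTAC experiment superposes arterial and venous sources", {
  res <- run_btac_experiment(tiny_btac_config())
  expect_named(res$runs, c("arterial", "venous", "combined"))
  s_a <- res$runs$arterial$singles_total
  s_v <- res$runs$venous$singles_total
  s_c <- res$runs$combined$singles_total
  expect_gt(s_a, 0); expect_gt(s_v, 0)
  # independent Poisson sources: combined = arterial + venous within
  # counting error
  expect_lt(abs(s_c - (s_a + s_v)), 5 * sqrt(s_c + s_a + s_v))
  # venous signal cannot precede the venous delay plus venous onset
  tr <- tracer("F18-fallypride")
  on_t <- tr$venous$t0 + tr$venous_delay
  expect_gte(min(res$runs$venous$sim$singles$time), on_t)
})

test_that("experiment outputs are bit-reproducible for a fixed config", {
  cfg <- tiny_btac_config()
  cfg$sim$horizon <- 220
  r1 <- run_btac_experiment(cfg, components = "arterial")
  r2 <- run_btac_experiment(cfg, components = "arterial")
  expect_identical(r1$runs$arterial$sim$singles,
                   r2$runs$arterial$sim$singles)
  expect_identical(r1$rates, r2$rates)
})

test_that("the NECR driver covers every configured source position", {
  cfg <- default_run_config("necr")
  cfg$necr$positions_y <- c(-1, -3)
  cfg$necr$n_windows <- 4
  cfg$necr$histories_per_window <- 3e3
  res <- run_necr_experiment(cfg)
  expect_named(res$experiments, c("Y=-1", "Y=-3"))
  expect_equal(length(unique(res$necr_points$position)), 2)
  expect_true(is.finite(res$summary$trues_ratio))
  expect_true(is.finite(res$summary$necr_max_ratio))
  expect_equal(nrow(res$experiments[["Y=-1"]]$points), 4)
  # rates identity holds in the per-window table
  pts <- res$necr_points
  expect_equal(pts$prompts, pts$trues + pts$scatters + pts$randoms)
})

test_that("ring scaling over a single ring count is the trivial table", {
  cfg <- default_run_config("rings")
  cfg$rings$ring_counts <- 1
  cfg$scale <- 0.0005
  cfg$sim$horizon <- 30
  res <- run_ring_scaling(cfg)
  expect_equal(nrow(res$gains), 1)
  expect_equal(res$gains$singles_gain, 1)
  expect_equal(res$gains$coincidence_gain, 1)
  expect_error({
    bad <- cfg; bad$rings$ring_counts <- c(1, 7)
    run_ring_scaling(bad)
  }, "1..4")
})

test_that("crystal comparison validates materials and ranks them", {
  cfg <- default_run_config("crystal")
  cfg$crystal$materials <- "BGO"
  cfg$scale <- 0.0005
  cfg$sim$horizon <- 20
  res <- run_crystal_comparison(cfg)
  expect_equal(res$summary$material, "BGO")
  bad <- cfg; bad$crystal$materials <- c("BGO", "NaI")
  expect_error(run_crystal_comparison(bad), "unknown crystal")
})

test_that("config files round-trip and unknown keys are rejected", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("experiment: rings", "seed: 7", "scale: 0.001",
               "rings:", "  ring_counts: [1, 2]"), cfg_file)
  cfg <- read_run_config(cfg_file)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$rings$ring_counts, c(1, 2))
  expect_equal(cfg$scanner$material, "BGO")   # default preserved
  bad_file <- withr::local_tempfile(fileext = ".json")
  writeLines('{"experiment": "btac", "bogus": 1}', bad_file)
  expect_error(read_run_config(bad_file), "unknown config entries")
})

test_that("run outputs carry seed and config hash metadata", {
  cfg <- default_run_config("rings")
  cfg$rings$ring_counts <- 1
  cfg$scale <- 0.0005
  cfg$sim$horizon <- 20
  res <- run_ring_scaling(cfg)
  out_dir <- withr::local_tempdir()
  write_run_outputs(res, out_dir)
  expect_true(file.exists(file.path(out_dir, "gains.csv")))
  expect_true(file.exists(file.path(out_dir, "summary.json")))
  hdr <- readLines(file.path(out_dir, "gains.csv"), n = 6)
  expect_true(any(grepl("^# seed: 1$", hdr)))
  expect_true(any(grepl("^# config_hash: ", hdr)))
  js <- jsonlite::read_json(file.path(out_dir, "summary.json"))
  expect_equal(js$seed, 1)
})

test_that("plot methods return ggplot objects", {
  cur <- aif_curve(tracer("O15-water")$arterial, step = 1, horizon = 150)
  expect_s3_class(autoplot(cur), "ggplot")
  sim <- list(singles = tibble::tibble(time = runif(50, 0, 5), block = 1L),
              coincidences = tibble::tibble(t1 = runif(9, 0, 5),
                                            class = "true"),
              t_range = c(0, 5))
  expect_s3_class(autoplot(bin_rates(sim, 1)), "ggplot")
})
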