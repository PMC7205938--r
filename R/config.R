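#' Default run configuration
#'
#' Nested list of every knob the experiment drivers read.  The `scale`
#' entry is the history scaling factor applied to BTAC source activities
#' (desk-scale runs); point-source experiments instead shorten acquisition
#' windows at full activity so that randoms and deadtime stay faithful.
#'
#' Schema (all entries optional in a user config; unknown entries error):
#' \preformatted{
#' experiment: "crystal" | "necr" | "btac" | "rings"
#' seed: integer
#' scale: numeric in (0, 1]
#' tracer: "O15-water" | "F18-fallypride"
#' scanner:
#'   material, n_rings, ring_inner_diameter, energy_window (keV pair),
#'   deadtime_factor, timing_jitter_ns
#' phantom: overrides passed to build_forearm_phantom()
#' flow:
#'   arterial: kind ("pulsatile"/"uniform"), v_sys, v_dia, width, period,
#'             mean (uniform)
#'   venous:   mean (cm/s), included (logical)
#' sim: horizon, time_step, segment_length, bin_width, chunk_decays
#' necr: positions_y (cm), a0_mbq, half_life_s, n_windows, n_half_lives,
#'       histories_per_window
#' rings: ring_counts
#' crystal: materials
#' }
#'
#' @param experiment One of `"crystal"`, `"necr"`, `"btac"`, `"rings"`.
#' @return A named list.
#' @export
default_run_config <- function(experiment = c("btac", "crystal", "necr",
                                              "rings")) {
  experiment <- match.arg(experiment)
  cfg <- list(
    experiment = experiment,
    seed = 1L,
    scale = 0.01,
    tracer = "O15-water",
    scanner = list(material = "BGO", n_rings = 1L,
                   ring_inner_diameter = 11, energy_window = c(350, 650),
                   deadtime_factor = 3, timing_jitter_ns = 1),
    phantom = NULL,
    flow = list(
      arterial = list(kind = "pulsatile", v_sys = 40, v_dia = 5,
                      width = 0.35, period = 1, mean = 15),
      venous = list(mean = 5, included = TRUE)
    ),
    sim = list(horizon = 60, time_step = 0.1, segment_length = 0.5,
               bin_width = 1, chunk_decays = 2e5),
    necr = list(positions_y = c(-1, -2, -3), a0_mbq = 14,
                half_life_s = 6586.2, n_windows = 12, n_half_lives = 5,
                histories_per_window = 6e4),
    rings = list(ring_counts = 1:4),
    crystal = list(materials = c("GSO", "LSO", "BGO", "CeBr3", "LaBr3"))
  )
  if (experiment == "crystal") {
    # closed-ring baseline: uniform 15 cm/s arterial flow, no venous return
    cfg$flow$arterial <- list(kind = "uniform", mean = 15)
    cfg$flow$venous$included <- FALSE
    cfg$scale <- 0.002
  }
  if (experiment == "rings") {
    cfg$scale <- 0.002
    cfg$sim$horizon <- 130
  }
  cfg
}

#' Read a run configuration file
#'
#' YAML or JSON (by extension), merged over [default_run_config()].
#'
#' @param path Config file path.
#' @return A config list.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- default_run_config(user$experiment %||% "btac")
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config entries: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  .deep_merge(base, user)
}

.config_hash <- function(config) rlang::hash(config)

.arterial_waveform <- function(flow_cfg) {
  a <- flow_cfg$arterial
  if (identical(a$kind, "uniform")) uniform_flow(a$mean)
  else pulsatile_flow(v_sys = a$v_sys, v_dia = a$v_dia, width = a$width,
                      period = a$period)
}

# metadata block prepended as comment lines to CSV outputs
.meta_header <- function(config, extra = NULL) {
  c(sprintf("# package: wristpet %s",
            as.character(utils::packageVersion("wristpet"))),
    sprintf("# experiment: %s", config$experiment),
    sprintf("# seed: %s", config$seed),
    sprintf("# scale: %s", config$scale),
    sprintf("# config_hash: %s", .config_hash(config)),
    extra)
}

#' Write experiment outputs to a directory
#'
#' Fixed layout: `rates.csv` (one row per bin and curve), `necr.csv` and
#' `gains.csv` where applicable, `summary.json`, `run.log`.  Every CSV
#' carries a comment header with the package version, seed, history scale
#' and config hash.
#'
#' @param result A result object from one of the `run_*` experiment
#'   drivers.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- result$config
  hdr <- .meta_header(config)
  put_csv <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  }
  if (!is.null(result$rates)) put_csv(result$rates, "rates.csv")
  if (!is.null(result$necr_points)) put_csv(result$necr_points, "necr.csv")
  if (!is.null(result$gains)) put_csv(result$gains, "gains.csv")
  jsonlite::write_json(
    c(result$summary,
      list(seed = config$seed, scale = config$scale,
           config_hash = .config_hash(config))),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(c(hdr, sprintf("# finished: %s",
                            format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}
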