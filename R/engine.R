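#' Sample decays from an activity timeline
#'
#' Each (segment, time-bin) row contributes a Poisson number of decays with
#' mean `activity * (t_hi - t_lo)`; decay times are uniform within the bin
#' and positions uniform within the segment cylinder.
#'
#' @param timeline Timeline tibble from [activity_timeline()],
#'   [btac_timeline()] or [point_source_timeline()].
#' @param id_offset Integer added to decay ids (used when sampling in
#'   chunks so ids stay globally unique).
#' @return A tibble of decays: `id`, `time` (s), `x`, `y`, `z` (cm),
#'   `source`.
#' @export
sample_decays <- function(timeline, id_offset = 0L) {
  stopifnot(is.data.frame(timeline))
  if (any(timeline$activity < 0)) stop("negative activity", call. = FALSE)
  counts <- rpois(nrow(timeline), timeline$activity *
                    (timeline$t_hi - timeline$t_lo))
  total <- sum(counts)
  if (total == 0L) {
    return(tibble(id = integer(), time = numeric(), x = numeric(),
                  y = numeric(), z = numeric(), source = character()))
  }
  row <- rep.int(seq_len(nrow(timeline)), counts)
  u_r <- sqrt(runif(total))
  phi <- runif(total, 0, 2 * pi)
  r <- timeline$radius[row] * u_r
  tibble(
    id = id_offset + seq_len(total),
    time = runif(total, timeline$t_lo[row], timeline$t_hi[row]),
    x = timeline$x[row] + r * cos(phi),
    y = timeline$y[row] + r * sin(phi),
    z = runif(total, timeline$z_lo[row], timeline$z_hi[row]),
    source = timeline$source[row]
  )
}

#' Emit back-to-back annihilation photon pairs
#'
#' Each decay produces two 511-keV photons from the decay position: the
#' first direction is uniform on the sphere, the second exactly
#' antiparallel.  Positron range and annihilation acollinearity are
#' neglected.
#'
#' @param decays Decay tibble from [sample_decays()].
#' @return A photon tibble with two rows per decay: `decay_id`, `photon`
#'   (1 or 2), `time`, `x`, `y`, `z`, `dx`, `dy`, `dz`, `energy` (keV).
#' @export
emit_annihilation <- function(decays) {
  n <- nrow(decays)
  d <- .sphere_directions(n)
  tibble(
    decay_id = rep(decays$id, 2L),
    photon = rep(1:2, each = n),
    time = rep(decays$time, 2L),
    x = rep(decays$x, 2L), y = rep(decays$y, 2L), z = rep(decays$z, 2L),
    dx = c(d[, 1], -d[, 1]), dy = c(d[, 2], -d[, 2]),
    dz = c(d[, 3], -d[, 3]),
    energy = 511
  )
}

#' Transport photons through the phantom
#'
#' Simplified 511-keV transport: the free path is sampled from the
#' exponential attenuation law along the segmented path through the
#' phantom volumes.  At an interaction the photon Compton-scatters with the
#' local material's `compton_fraction` (otherwise it is absorbed); the
#' scattering angle is sampled from the Klein-Nishina distribution at the
#' current energy and the energy updated with the Compton formula.  At most
#' one scatter is followed: a second interaction absorbs the photon.
#'
#' @param photons Photon tibble from [emit_annihilation()].
#' @param phantom A [phantom_model()].
#' @return The photon tibble with positions/directions/energies updated and
#'   columns `outcome` (`"escaped"` or `"absorbed"`) and `scattered`
#'   (logical) appended.  Background outside the phantom volumes is treated
#'   as vacuum.
#' @export
transport_photon <- function(photons, phantom) {
  stopifnot(inherits(phantom, "phantom_model"))
  cp <- .compile_phantom(phantom)
  n <- nrow(photons)
  ox <- photons$x; oy <- photons$y; oz <- photons$z
  dx <- photons$dx; dy <- photons$dy; dz <- photons$dz
  energy <- photons$energy
  scattered <- logical(n)
  outcome <- rep("escaped", n)

  iv <- .ray_intervals(cp, ox, oy, oz, dx, dy, dz)
  tau_tot <- .tau_total(cp, iv)
  xi <- rexp(n)
  interact <- xi < tau_tot
  idx <- which(interact)
  if (length(idx) > 0L) {
    thi_sub <- iv$thi[idx, , drop = FALSE]
    t_max <- thi_sub[, 1L]
    for (v in seq_len(ncol(thi_sub))[-1L]) t_max <- pmax(t_max, thi_sub[, v])
    t_star <- .invert_tau(
      cp,
      list(tlo = iv$tlo[idx, , drop = FALSE],
           thi = iv$thi[idx, , drop = FALSE]),
      xi[idx], t_max
    )
    px <- ox[idx] + t_star * dx[idx]
    py <- oy[idx] + t_star * dy[idx]
    pz <- oz[idx] + t_star * dz[idx]
    cf <- .compton_fraction_at(cp, px, py, pz)
    is_compton <- runif(length(idx)) < cf
    outcome[idx[!is_compton]] <- "absorbed"
    ci <- idx[is_compton]
    if (length(ci) > 0L) {
      sel <- which(is_compton)
      cost <- .sample_kn_cos(energy[ci])
      new_d <- .rotate_rows(cbind(dx[ci], dy[ci], dz[ci]), cost)
      new_e <- energy[ci] / (1 + (energy[ci] / 511) * (1 - cost))
      ox[ci] <- px[sel]; oy[ci] <- py[sel]; oz[ci] <- pz[sel]
      dx[ci] <- new_d[, 1]; dy[ci] <- new_d[, 2]; dz[ci] <- new_d[, 3]
      energy[ci] <- new_e
      scattered[ci] <- TRUE
      iv2 <- .ray_intervals(cp, ox[ci], oy[ci], oz[ci],
                            dx[ci], dy[ci], dz[ci])
      # energy dependence of mu between 511 and ~170 keV is neglected:
      # the scattered photon sees the same attenuation coefficients
      tau2 <- .tau_total(cp, iv2)
      absorbed2 <- rexp(length(ci)) < tau2
      outcome[ci[absorbed2]] <- "absorbed"
    }
  }
  out <- photons
  out$x <- ox; out$y <- oy; out$z <- oz
  out$dx <- dx; out$dy <- dy; out$dz <- dz
  out$energy <- energy
  out$scattered <- scattered
  out$outcome <- outcome
  out
}

#' Detect escaped photons on the scanner blocks
#'
#' The first block intersected along each photon's ray is tested with
#' [detection_probability()] for the chord length in that block; on
#' success the deposited energy is blurred with [blur_energy()] and the
#' event kept iff [apply_energy_window()] accepts.  The timestamp is the
#' decay time plus Gaussian timing jitter (photon time of flight is
#' neglected).  Deadtime is *not* applied here; see [simulate_run()].
#'
#' @param photons Transported photon tibble (rows with
#'   `outcome == "escaped"` are considered).
#' @param scanner A [build_wristpet1()] / [build_wristpet2()] scanner.
#' @return A singles tibble: `time` (s), `block`, `energy` (keV,
#'   post-blur), `decay_id`, `scattered`, sorted by time.
#' @export
detect_photon <- function(photons, scanner) {
  stopifnot(inherits(scanner, "scanner_config"))
  if ("outcome" %in% names(photons)) {
    photons <- photons[photons$outcome == "escaped", , drop = FALSE]
  }
  n <- nrow(photons)
  if (n == 0L) {
    return(tibble(time = numeric(), block = integer(), energy = numeric(),
                  decay_id = integer(), scattered = logical()))
  }
  scat_flag <- if ("scattered" %in% names(photons)) photons$scattered
  else rep(FALSE, n)
  hit <- .first_block_hit(scanner, photons$x, photons$y, photons$z,
                          photons$dx, photons$dy, photons$dz)
  p <- detection_probability(hit$pathlength, scanner$material)
  detected <- hit$block > 0L & runif(n) < p
  if (!any(detected)) {
    return(tibble(time = numeric(), block = integer(), energy = numeric(),
                  decay_id = integer(), scattered = logical()))
  }
  e_blur <- blur_energy(photons$energy[detected], scanner$material)
  keep <- apply_energy_window(e_blur, scanner$energy_window)
  t_out <- photons$time[detected][keep] +
    rnorm(sum(keep), sd = scanner$timing_jitter_ns * 1e-9)
  out <- tibble(
    time = t_out,
    block = hit$block[detected][keep],
    energy = e_blur[keep],
    decay_id = photons$decay_id[detected][keep],
    scattered = scat_flag[detected][keep]
  )
  arrange(out, .data$time)
}

#' Sort singles into coincidences
#'
#' Implements the "keep if all are good" multiple-coincidence policy: a
#' window opens at the earliest unconsumed single and collects every single
#' within the coincidence window.  Two collected singles on different
#' blocks form one coincidence; when more than two are collected, all pairs
#' are emitted only if every pair is good (all singles on distinct blocks),
#' otherwise the whole multiple is discarded.  Consumed singles are never
#' reused.
#'
#' @param singles Singles tibble sorted by time, with deadtime already
#'   applied.
#' @param window Coincidence window, s.
#' @return A coincidence tibble: `t1`, `t2`, `block1`, `block2`,
#'   `decay_id1`, `decay_id2`, `scattered1`, `scattered2`.
#' @export
sort_coincidences <- function(singles, window) {
  .assert_scalar_num(window, "window", lower = 0)
  tm <- singles$time
  if (is.unsorted(tm)) stop("singles must be sorted by time", call. = FALSE)
  n <- length(tm)
  out_i <- integer(0); out_j <- integer(0)
  if (n >= 2L) {
    last_in <- findInterval(tm + window, tm)
    cap <- max(64L, n)
    out_i <- integer(cap); out_j <- integer(cap); m <- 0L
    blocks <- singles$block
    i <- 1L
    while (i <= n) {
      k <- last_in[i]
      cnt <- k - i + 1L
      if (cnt == 2L) {
        if (blocks[i] != blocks[i + 1L]) {
          m <- m + 1L
          if (m > length(out_i)) {
            length(out_i) <- 2L * length(out_i)
            length(out_j) <- 2L * length(out_j)
          }
          out_i[m] <- i; out_j[m] <- i + 1L
        }
      } else if (cnt > 2L) {
        grp <- i:k
        if (!anyDuplicated(blocks[grp])) {
          prs <- combn(grp, 2L)
          np <- ncol(prs)
          while (m + np > length(out_i)) {
            length(out_i) <- 2L * length(out_i)
            length(out_j) <- 2L * length(out_j)
          }
          out_i[(m + 1L):(m + np)] <- prs[1L, ]
          out_j[(m + 1L):(m + np)] <- prs[2L, ]
          m <- m + np
        }
      }
      i <- k + 1L
    }
    out_i <- out_i[seq_len(m)]; out_j <- out_j[seq_len(m)]
  }
  tibble(
    t1 = tm[out_i], t2 = tm[out_j],
    block1 = singles$block[out_i], block2 = singles$block[out_j],
    decay_id1 = singles$decay_id[out_i], decay_id2 = singles$decay_id[out_j],
    scattered1 = singles$scattered[out_i],
    scattered2 = singles$scattered[out_j]
  )
}

#' Classify coincidences as true, scattered or random
#'
#' Both singles from the same decay and neither phantom-scattered: true.
#' Same decay with at least one scattered photon: scattered.  Different
#' decays: random.
#'
#' @param coincidences Tibble from [sort_coincidences()].
#' @return The tibble with a `class` column
#'   (`"true"`/`"scattered"`/`"random"`).
#' @export
classify_coincidence <- function(coincidences) {
  same <- coincidences$decay_id1 == coincidences$decay_id2
  any_scat <- coincidences$scattered1 | coincidences$scattered2
  coincidences$class <- ifelse(!same, "random",
                               ifelse(any_scat, "scattered", "true"))
  coincidences
}

#' Run a full simulation: decays to classified coincidences
#'
#' Chains [sample_decays()], [emit_annihilation()], [transport_photon()]
#' and [detect_photon()] in memory-bounded chunks, then applies
#' per-block non-paralyzable deadtime ([apply_deadtime()]), sorts
#' coincidences ([sort_coincidences()]) and classifies them.  With a fixed
#' `seed`, results are bit-reproducible.
#'
#' @param timeline Activity timeline tibble (Bq).
#' @param phantom A [phantom_model()].
#' @param scanner A `scanner_config`.
#' @param seed Optional integer seed for the run's RNG stream.
#' @param chunk_decays Approximate decays processed per chunk.
#' @return An object of class `coincidence_sim`: a list with `singles`,
#'   `coincidences` (classified), `n_decays`, `duration` (total source
#'   time span, s), `seed`, and the scanner/phantom descriptions.
#' @export
simulate_run <- function(timeline, phantom, scanner, seed = NULL,
                         chunk_decays = 2e5) {
  if (!is.null(seed)) set.seed(seed)
  expected <- timeline$activity * (timeline$t_hi - timeline$t_lo)
  grp <- floor(cumsum(expected) / chunk_decays)
  chunks <- split(seq_len(nrow(timeline)), grp)
  singles_list <- vector("list", length(chunks))
  n_decays <- 0L
  for (ci in seq_along(chunks)) {
    decays <- sample_decays(timeline[chunks[[ci]], , drop = FALSE],
                            id_offset = n_decays)
    n_decays <- n_decays + nrow(decays)
    if (nrow(decays) == 0L) next
    photons <- emit_annihilation(decays)
    photons <- transport_photon(photons, phantom)
    singles_list[[ci]] <- detect_photon(photons, scanner)
  }
  singles <- bind_rows(singles_list)
  if (nrow(singles) > 0L) {
    singles <- arrange(singles, .data$block, .data$time)
    tau_s <- scanner$deadtime_ns * 1e-9
    keep <- unlist(lapply(
      split(singles$time, singles$block),
      apply_deadtime, tau = tau_s
    ), use.names = FALSE)
    singles <- singles[keep, , drop = FALSE]
    singles <- arrange(singles, .data$time)
  }
  coinc <- sort_coincidences(singles, scanner$coincidence_window_ns * 1e-9)
  coinc <- classify_coincidence(coinc)
  structure(
    list(singles = singles, coincidences = coinc,
         n_decays = n_decays,
         duration = sum(tapply(timeline$t_hi - timeline$t_lo,
                               paste(timeline$t_lo, timeline$t_hi),
                               `[`, 1L)),
         t_range = range(timeline$t_lo, timeline$t_hi),
         seed = seed, scanner_name = scanner$name,
         material = scanner$material$name,
         n_rings = scanner$n_axial_rings),
    class = "coincidence_sim"
  )
}

#' @export
print.coincidence_sim <- function(x, ...) {
  cls <- table(factor(x$coincidences$class,
                      levels = c("true", "scattered", "random")))
  cat(sprintf("<coincidence_sim> %s (%s, %d ring): %s decays -> %s singles, %s coincidences (T %s / S %s / R %s)\n",
              x$scanner_name, x$material, x$n_rings,
              format(x$n_decays, big.mark = ","),
              format(nrow(x$singles), big.mark = ","),
              format(nrow(x$coincidences), big.mark = ","),
              cls[1], cls[2], cls[3]))
  invisible(x)
}
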