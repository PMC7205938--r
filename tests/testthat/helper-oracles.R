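# Independent oracles used to validate the geometric and statistical
# machinery.  These deliberately avoid the code paths they check: the ray
# oracles classify dense sample points, and the coincidence oracle walks
# the policy definition event by event.

# dense ray-marching through a phantom: classify the material at points
# spaced `step` cm along the ray and run-length-encode the result
oracle_trace <- function(phantom, origin, direction, max_length,
                         step = 1e-3) {
  d <- direction / sqrt(sum(direction^2))
  t <- seq(step / 2, max_length, by = step)
  px <- origin[1] + t * d[1]
  py <- origin[2] + t * d[2]
  pz <- origin[3] + t * d[3]
  mat <- rep(NA_character_, length(t))
  best_pri <- rep(-Inf, length(t))
  for (v in phantom$volumes) {
    inside <- (px - v$center[1])^2 + (py - v$center[2])^2 < v$radius^2 &
      abs(pz) <= v$length / 2
    take <- inside & v$priority > best_pri
    mat[take] <- v$material$name
    best_pri[take] <- v$priority
  }
  r <- rle(mat)
  keep <- !is.na(r$values)
  data.frame(material = r$values[keep],
             pathlength = r$lengths[keep] * step)
}

# dense ray-marching chord length through one oriented detector block
oracle_block_chord <- function(block, origin, direction, max_length = 25,
                               step = 1e-3,
                               dims = c(tangential = 2.45, axial = 3.0,
                                        radial = 2.0)) {
  d <- direction / sqrt(sum(direction^2))
  t <- seq(step / 2, max_length, by = step)
  px <- origin[1] + t * d[1] - block$cx
  py <- origin[2] + t * d[2] - block$cy
  pz <- origin[3] + t * d[3] - block$cz
  a <- block$azimuth_deg * pi / 180
  lr <- px * (-cos(a)) + py * (-sin(a))
  lt <- px * (-sin(a)) + py * cos(a)
  inside <- abs(lr) <= dims[["radial"]] / 2 &
    abs(lt) <= dims[["tangential"]] / 2 &
    abs(pz) <= dims[["axial"]] / 2
  sum(inside) * step
}

# literal walk of the "keep if all are good" coincidence policy
oracle_sorter <- function(times, blocks, window) {
  ord <- order(times)
  times <- times[ord]; blocks <- blocks[ord]
  pairs <- list()
  i <- 1L
  n <- length(times)
  while (i <= n) {
    grp <- which(times >= times[i] & times <= times[i] + window)
    grp <- grp[grp >= i]
    if (length(grp) == 2L) {
      if (blocks[grp[1]] != blocks[grp[2]]) {
        pairs[[length(pairs) + 1L]] <- times[grp]
      }
    } else if (length(grp) > 2L) {
      if (!anyDuplicated(blocks[grp])) {
        cmb <- combn(grp, 2L)
        for (k in seq_len(ncol(cmb))) {
          pairs[[length(pairs) + 1L]] <- times[cmb[, k]]
        }
      }
    }
    i <- max(grp) + 1L
  }
  pairs
}

# aif_params holding a constant concentration C for all t >= 0
constant_aif <- function(C, unit = "Bq/ml") {
  aif_params(a = 1, b = C, c1 = C, c2 = 0, d1 = 0, d2 = 0,
             t0 = 0, t1 = 0, unit = unit)
}

# timeline for a steady point-like source at constant activity
steady_source_timeline <- function(activity_bq, duration, n_windows = 1L,
                                   position = c(0, 0, 0), radius = 0.05,
                                   height = 0.1) {
  edges <- seq(0, duration, length.out = n_windows + 1L)
  tibble::tibble(
    source = "steady", segment = seq_len(n_windows),
    x = position[1], y = position[2], radius = radius,
    z_lo = position[3] - height / 2, z_hi = position[3] + height / 2,
    t_lo = edges[-length(edges)], t_hi = edges[-1],
    activity = activity_bq
  )
}

# photon tibble builder for direct transport/detection tests
make_photons <- function(n, origin, direction, energy = 511, time = 0) {
  d <- direction / sqrt(sum(direction^2))
  tibble::tibble(
    decay_id = seq_len(n), photon = 1L, time = time,
    x = origin[1], y = origin[2], z = origin[3],
    dx = d[1], dy = d[2], dz = d[3], energy = energy
  )
}
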