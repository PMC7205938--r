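# Vectorised transport internals.
#
# All phantom volumes are z-aligned cylinders, and inner volumes (bones,
# vessels) lie strictly inside the body cylinder without overlapping each
# other.  The optical depth along any ray is therefore
#   tau(t) = mu_body * len_body(t) + sum_v (mu_v - mu_body) * len_v(t)
# with len_v(t) the clipped chord of the ray in volume v up to parameter t.
# This "delta-mu" decomposition is exact for the phantom invariants enforced
# by phantom_model() and keeps the per-photon cost at a handful of vector
# operations per volume.

.compile_phantom <- function(phantom) {
  vols <- phantom$volumes
  body <- vols[[phantom$body_index]]
  mu_body <- body$material$mu_511
  dmu <- vapply(seq_along(vols), function(i) {
    if (i == phantom$body_index) mu_body
    else vols[[i]]$material$mu_511 - mu_body
  }, numeric(1))
  list(
    cx = vapply(vols, function(v) v$center[1], numeric(1)),
    cy = vapply(vols, function(v) v$center[2], numeric(1)),
    r = vapply(vols, `[[`, numeric(1), "radius"),
    zlo = vapply(vols, function(v) -v$length / 2, numeric(1)),
    zhi = vapply(vols, function(v) v$length / 2, numeric(1)),
    dmu = dmu,
    mu = vapply(vols, function(v) v$material$mu_511, numeric(1)),
    cf = vapply(vols, function(v) v$material$compton_fraction, numeric(1)),
    pri = vapply(vols, `[[`, integer(1), "priority"),
    body_index = phantom$body_index
  )
}

# per-volume ray intervals: returns list(tlo, thi) of n x V matrices,
# already clipped to t >= 0 (empty intervals have thi <= tlo)
.ray_intervals <- function(cp, ox, oy, oz, dx, dy, dz) {
  n <- length(ox); V <- length(cp$r)
  tlo <- matrix(0, n, V); thi <- matrix(0, n, V)
  for (v in seq_len(V)) {
    fx <- ox - cp$cx[v]; fy <- oy - cp$cy[v]
    a <- dx * dx + dy * dy
    b <- fx * dx + fy * dy
    cc <- fx * fx + fy * fy - cp$r[v]^2
    disc <- b * b - a * cc
    sq <- sqrt(pmax(disc, 0))
    axial <- a < 1e-14
    t1 <- ifelse(axial, ifelse(cc < 0, -Inf, Inf), (-b - sq) / pmax(a, 1e-300))
    t2 <- ifelse(axial, ifelse(cc < 0, Inf, -Inf), (-b + sq) / pmax(a, 1e-300))
    miss <- !axial & disc <= 0
    t1[miss] <- Inf; t2[miss] <- -Inf
    # z-slab clip
    vertical <- abs(dz) < 1e-14
    zo_in <- oz >= cp$zlo[v] & oz <= cp$zhi[v]
    za <- (cp$zlo[v] - oz) / ifelse(vertical, 1, dz)
    zb <- (cp$zhi[v] - oz) / ifelse(vertical, 1, dz)
    z1 <- ifelse(vertical, ifelse(zo_in, -Inf, Inf), pmin(za, zb))
    z2 <- ifelse(vertical, ifelse(zo_in, Inf, -Inf), pmax(za, zb))
    tlo[, v] <- pmax(t1, z1, 0)
    thi[, v] <- pmax(pmin(t2, z2), 0)
  }
  list(tlo = tlo, thi = thi)
}

# optical depth from t = 0 up to parameter t (vector), given intervals
.tau_at <- function(cp, iv, t) {
  tau <- numeric(length(t))
  for (v in seq_along(cp$dmu)) {
    tau <- tau + cp$dmu[v] *
      pmax(0, pmin(t, iv$thi[, v]) - iv$tlo[, v])
  }
  tau
}

.tau_total <- function(cp, iv) {
  tau <- 0
  for (v in seq_along(cp$dmu)) {
    tau <- tau + cp$dmu[v] * pmax(0, iv$thi[, v] - iv$tlo[, v])
  }
  tau
}

# invert tau(t) = target by bisection; rays are guaranteed tau_total >= target
.invert_tau <- function(cp, iv, target, t_max) {
  lo <- numeric(length(target)); hi <- t_max
  for (i in seq_len(48L)) {
    mid <- (lo + hi) / 2
    below <- .tau_at(cp, iv, mid) < target
    lo[below] <- mid[below]; hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

# Compton fraction of the highest-priority volume containing each point
.compton_fraction_at <- function(cp, x, y, z) {
  n <- length(x)
  best_pri <- rep(-Inf, n)
  cf <- rep(cp$cf[cp$body_index], n)   # default: body material
  for (v in seq_along(cp$r)) {
    inside <- (x - cp$cx[v])^2 + (y - cp$cy[v])^2 < cp$r[v]^2 &
      z >= cp$zlo[v] & z <= cp$zhi[v]
    take <- inside & cp$pri[v] > best_pri
    best_pri[take] <- cp$pri[v]
    cf[take] <- cp$cf[v]
  }
  cf
}

# Klein-Nishina sampling of the scattering angle cosine at energies E (keV),
# by rejection against a uniform proposal on [-1, 1]
.sample_kn_cos <- function(energy) {
  n <- length(energy)
  out <- numeric(n)
  todo <- seq_len(n)
  alpha <- energy / 511
  guard <- 0L
  while (length(todo) > 0L && guard < 1000L) {
    a <- alpha[todo]
    mu <- runif(length(todo), -1, 1)
    r <- 1 / (1 + a * (1 - mu))
    f <- r^2 * (r + 1 / r - (1 - mu^2))   # <= 2 everywhere
    acc <- runif(length(todo)) * 2 <= f
    out[todo[acc]] <- mu[acc]
    todo <- todo[!acc]
    guard <- guard + 1L
  }
  if (length(todo) > 0L) out[todo] <- runif(length(todo), -1, 1)
  out
}

# rotate unit rows of `d` by polar angle acos(cost) about a uniform azimuth
.rotate_rows <- function(d, cost) {
  n <- nrow(d)
  sint <- sqrt(pmax(0, 1 - cost^2))
  psi <- runif(n, 0, 2 * pi)
  # orthonormal frame: e1 = d x a / |.|, a = z-hat (x-hat where d ~ z-hat)
  use_x <- abs(d[, 3]) > 0.9
  ax <- ifelse(use_x, 1, 0); az <- ifelse(use_x, 0, 1)
  e1x <- d[, 2] * az
  e1y <- d[, 3] * ax - d[, 1] * az
  e1z <- -d[, 2] * ax
  nrm <- sqrt(e1x^2 + e1y^2 + e1z^2)
  e1x <- e1x / nrm; e1y <- e1y / nrm; e1z <- e1z / nrm
  e2x <- d[, 2] * e1z - d[, 3] * e1y
  e2y <- d[, 3] * e1x - d[, 1] * e1z
  e2z <- d[, 1] * e1y - d[, 2] * e1x
  cp <- cos(psi); sp <- sin(psi)
  cbind(cost * d[, 1] + sint * (cp * e1x + sp * e2x),
        cost * d[, 2] + sint * (cp * e1y + sp * e2y),
        cost * d[, 3] + sint * (cp * e1z + sp * e2z))
}

# vectorised ray/box first-hit against all scanner blocks:
# returns list(block = id or 0, pathlength)
.first_block_hit <- function(scanner, ox, oy, oz, dx, dy, dz) {
  bl <- scanner$blocks
  half_r <- scanner$block_dims[["radial"]] / 2
  half_t <- scanner$block_dims[["tangential"]] / 2
  half_a <- scanner$block_dims[["axial"]] / 2
  n <- length(ox)
  best_t <- rep(Inf, n)
  best_len <- numeric(n)
  best_block <- integer(n)
  for (b in seq_len(nrow(bl))) {
    a <- bl$azimuth_deg[b] * pi / 180
    nrx <- -cos(a); nry <- -sin(a)
    tgx <- -sin(a); tgy <- cos(a)
    pox <- ox - bl$cx[b]; poy <- oy - bl$cy[b]; poz <- oz - bl$cz[b]
    lo1 <- pox * nrx + poy * nry
    lo2 <- pox * tgx + poy * tgy
    lo3 <- poz
    ld1 <- dx * nrx + dy * nry
    ld2 <- dx * tgx + dy * tgy
    ld3 <- dz
    tin <- rep(-Inf, n); tout <- rep(Inf, n)
    for (axis in 1:3) {
      lo <- switch(axis, lo1, lo2, lo3)
      ld <- switch(axis, ld1, ld2, ld3)
      half <- switch(axis, half_r, half_t, half_a)
      par <- abs(ld) < 1e-12
      lds <- ifelse(par, 1, ld)
      ta <- (-half - lo) / lds
      tb <- (half - lo) / lds
      a1 <- ifelse(par, ifelse(abs(lo) <= half, -Inf, Inf), pmin(ta, tb))
      a2 <- ifelse(par, ifelse(abs(lo) <= half, Inf, -Inf), pmax(ta, tb))
      tin <- pmax(tin, a1); tout <- pmin(tout, a2)
    }
    tin <- pmax(tin, 0)
    hit <- tout > tin & is.finite(tin)
    upd <- hit & tin < best_t
    best_t[upd] <- tin[upd]
    best_len[upd] <- (tout - tin)[upd]
    best_block[upd] <- bl$id[b]
  }
  list(block = best_block, pathlength = best_len)
}
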