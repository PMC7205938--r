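#' Define a z-aligned cylindrical volume
#'
#' All phantom volumes are right circular cylinders with their axis parallel
#' to Z, specified by a transaxial centre, radius and axial length (centred
#' on z = 0).  Where volumes overlap, the highest `priority` wins.
#'
#' @param label Volume label (e.g. `"artery_radial"`).
#' @param center Length-2 numeric, (x, y) centre in cm.
#' @param radius Cylinder radius, cm.
#' @param length Axial length, cm (the cylinder spans `[-length/2, length/2]`).
#' @param material A [material()] object.
#' @param priority Integer; higher priority resolves overlaps.
#' @param role One of `"body"`, `"bone"`, `"artery"`, `"vein"`, `"source"`,
#'   `"other"`; used for phantom invariant checks and flow attachment.
#' @return An object of class `cylinder_volume`.
#' @export
cylinder_volume <- function(label, center, radius, length, material,
                            priority,
                            role = c("other", "body", "bone", "artery",
                                     "vein", "source")) {
  role <- match.arg(role)
  stopifnot(is.character(label), length(label) == 1L,
            is.numeric(center), length(center) == 2L,
            inherits(material, "pet_material"))
  .assert_scalar_num(radius, "radius", lower = 0, allow_zero = FALSE)
  .assert_scalar_num(length, "length", lower = 0, allow_zero = FALSE)
  .assert_scalar_num(priority, "priority")
  structure(
    list(label = label, center = as.numeric(center), radius = radius,
         length = length, material = material,
         priority = as.integer(priority), role = role),
    class = "cylinder_volume"
  )
}

#' Assemble a phantom from cylindrical volumes
#'
#' The volume with role `"body"` is the enclosing medium (the arm); every
#' other volume must lie entirely inside it.  Arteries and veins must not
#' intersect bones, volumes must not share a priority, and inner volumes
#' must be pairwise disjoint.
#'
#' @param volumes List of [cylinder_volume()] objects.
#' @param background [material()] for the space outside all volumes.
#'   Treated as non-attenuating by the transport step.
#' @return An object of class `phantom_model`.
#' @export
phantom_model <- function(volumes, background = default_materials()$air) {
  stopifnot(length(volumes) >= 1L,
            all(vapply(volumes, inherits, logical(1), "cylinder_volume")))
  pri <- vapply(volumes, `[[`, integer(1), "priority")
  if (anyDuplicated(pri)) {
    stop("invalid geometry: volume priorities must be unique", call. = FALSE)
  }
  roles <- vapply(volumes, `[[`, character(1), "role")
  body_idx <- which(roles == "body")
  if (length(body_idx) != 1L) {
    stop("phantom needs exactly one volume with role 'body'", call. = FALSE)
  }
  body <- volumes[[body_idx]]
  inner <- volumes[-body_idx]
  for (v in inner) {
    d <- sqrt(sum((v$center - body$center)^2))
    if (d + v$radius > body$radius + 1e-9 || v$length > body$length + 1e-9) {
      stop(sprintf("invalid geometry: volume '%s' extends outside the body cylinder",
                   v$label), call. = FALSE)
    }
  }
  # pairwise disjointness of inner volumes (transaxially; all share z = 0 centre)
  if (length(inner) > 1L) {
    for (i in seq_len(length(inner) - 1L)) {
      for (j in seq(i + 1L, length(inner))) {
        a <- inner[[i]]; b <- inner[[j]]
        d <- sqrt(sum((a$center - b$center)^2))
        if (d < a$radius + b$radius - 1e-9) {
          stop(sprintf("invalid geometry: volumes '%s' and '%s' intersect",
                       a$label, b$label), call. = FALSE)
        }
      }
    }
  }
  structure(list(volumes = volumes, background = background,
                 body_index = body_idx),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat(sprintf("<phantom_model> %d volumes (background: %s)\n",
              length(x$volumes), x$background$name))
  print(as_tibble(x))
  invisible(x)
}

#' @export
as_tibble.phantom_model <- function(x, ...) {
  vols <- x$volumes
  tibble(
    label = vapply(vols, `[[`, character(1), "label"),
    role = vapply(vols, `[[`, character(1), "role"),
    x = vapply(vols, function(v) v$center[1], numeric(1)),
    y = vapply(vols, function(v) v$center[2], numeric(1)),
    radius = vapply(vols, `[[`, numeric(1), "radius"),
    length = vapply(vols, `[[`, numeric(1), "length"),
    material = vapply(vols, function(v) v$material$name, character(1)),
    mu_511 = vapply(vols, function(v) v$material$mu_511, numeric(1)),
    priority = vapply(vols, `[[`, integer(1), "priority")
  )
}

#' Build the default forearm phantom
#'
#' A water cylinder 20 cm long and 8 cm in diameter holds two 2.5-cm-diameter
#' bone cylinders (radius and ulna), two 2.5-mm-diameter blood cylinders
#' (radial and ulnar arteries) and two 1.5-mm-diameter blood cylinders
#' (radial and ulnar veins), all parallel to Z.  The bone centres sit at
#' (+/-1.8, +0.5) cm, giving a 1.1 cm surface-to-surface bone gap; arteries
#' at (-/+2.0, -2.5) cm and veins at (+/-2.4, -2.5) cm place the vessels on
#' the volar (negative Y) aspect.  Overlap priority is
#' vessels > bones > arm.
#'
#' @param config Optional nested list of overrides with elements `arm`
#'   (`radius`, `length`, `center`), `bones`, `arteries`, `veins` (each with
#'   `radius` and `centers`, a list of (x, y) pairs), and `materials`
#'   (passed to [default_materials()]).
#' @return A [phantom_model()].
#' @examples
#' ph <- build_forearm_phantom()
#' as_tibble(ph)
#' @export
build_forearm_phantom <- function(config = NULL) {
  geo <- list(
    arm = list(radius = 4.0, length = 20.0, center = c(0, 0)),
    bones = list(radius = 1.25,
                 centers = list(c(-1.8, 0.5), c(1.8, 0.5))),
    arteries = list(radius = 0.125,
                    centers = list(c(-2.0, -2.5), c(2.0, -2.5))),
    veins = list(radius = 0.075,
                 centers = list(c(-2.4, -2.5), c(2.4, -2.5))),
    materials = NULL
  )
  geo <- .deep_merge(geo, config)
  mats <- default_materials(geo$materials)
  L <- geo$arm$length
  vols <- list(
    cylinder_volume("arm", geo$arm$center, geo$arm$radius, L, mats$water,
                    priority = 1L, role = "body"),
    cylinder_volume("bone_radius", geo$bones$centers[[1]], geo$bones$radius,
                    L, mats$bone, priority = 2L, role = "bone"),
    cylinder_volume("bone_ulna", geo$bones$centers[[2]], geo$bones$radius,
                    L, mats$bone, priority = 3L, role = "bone"),
    cylinder_volume("artery_radial", geo$arteries$centers[[1]],
                    geo$arteries$radius, L, mats$blood, priority = 4L,
                    role = "artery"),
    cylinder_volume("artery_ulnar", geo$arteries$centers[[2]],
                    geo$arteries$radius, L, mats$blood, priority = 5L,
                    role = "artery"),
    cylinder_volume("vein_radial", geo$veins$centers[[1]], geo$veins$radius,
                    L, mats$blood, priority = 6L, role = "vein"),
    cylinder_volume("vein_ulnar", geo$veins$centers[[2]], geo$veins$radius,
                    L, mats$blood, priority = 7L, role = "vein")
  )
  phantom_model(vols, background = mats$air)
}

#' Build a uniform water cylinder phantom
#'
#' Used for the decaying-point-source count-rate experiments: a water-only
#' cylinder (default 8 cm diameter, 20 cm long) with no internal structure.
#'
#' @param diameter,length Cylinder dimensions, cm.
#' @param materials Optional material overrides (see [default_materials()]).
#' @return A [phantom_model()].
#' @export
build_water_phantom <- function(diameter = 8, length = 20, materials = NULL) {
  mats <- default_materials(materials)
  phantom_model(
    list(cylinder_volume("water", c(0, 0), diameter / 2, length, mats$water,
                         priority = 1L, role = "body")),
    background = mats$air
  )
}

# ray/cylinder intersection for one z-aligned cylinder; returns c(tlo, thi)
# in the 3-D ray parameter (empty interval when thi < tlo)
.ray_cylinder_interval_1 <- function(o, d, cx, cy, r, zlo, zhi) {
  fx <- o[1] - cx; fy <- o[2] - cy
  a <- d[1]^2 + d[2]^2
  if (a < 1e-14) {
    if (fx^2 + fy^2 < r^2) { t1 <- -Inf; t2 <- Inf } else return(c(1, 0))
  } else {
    b <- fx * d[1] + fy * d[2]
    cc <- fx^2 + fy^2 - r^2
    disc <- b^2 - a * cc
    if (disc <= 0) return(c(1, 0))
    sq <- sqrt(disc)
    t1 <- (-b - sq) / a; t2 <- (-b + sq) / a
  }
  if (abs(d[3]) < 1e-14) {
    if (o[3] < zlo || o[3] > zhi) return(c(1, 0))
  } else {
    z1 <- (zlo - o[3]) / d[3]; z2 <- (zhi - o[3]) / d[3]
    t1 <- max(t1, min(z1, z2)); t2 <- min(t2, max(z1, z2))
  }
  c(t1, t2)
}

#' Trace a ray through a phantom
#'
#' Returns the ordered material segments a ray traverses inside the phantom
#' volumes, with overlaps resolved by volume priority.  Background (outside
#' every volume) is not reported.
#'
#' @param phantom A [phantom_model()].
#' @param origin Length-3 numeric, ray origin in cm.
#' @param direction Length-3 numeric; normalised internally, error on zero.
#' @param max_length Maximum traced pathlength, cm.
#' @return A tibble with columns `material`, `mu_511`, `compton_fraction`
#'   and `pathlength` (cm), ordered along the ray.
#' @examples
#' ph <- build_forearm_phantom()
#' trace_path(ph, c(0, -6, 0), c(0, 1, 0), 20) # 8 cm water chord + bone
#' @export
trace_path <- function(phantom, origin, direction, max_length = 50) {
  stopifnot(inherits(phantom, "phantom_model"),
            is.numeric(origin), length(origin) == 3L,
            is.numeric(direction), length(direction) == 3L)
  .assert_scalar_num(max_length, "max_length", lower = 0, allow_zero = FALSE)
  d <- .normalize3(direction)
  vols <- phantom$volumes
  iv <- lapply(vols, function(v) {
    .ray_cylinder_interval_1(origin, d, v$center[1], v$center[2], v$radius,
                             -v$length / 2, v$length / 2)
  })
  lo <- pmax(vapply(iv, `[[`, numeric(1), 1), 0)
  hi <- pmin(vapply(iv, `[[`, numeric(1), 2), max_length)
  keep <- hi > lo + 1e-12
  if (!any(keep)) {
    return(tibble(material = character(), mu_511 = numeric(),
                  compton_fraction = numeric(), pathlength = numeric()))
  }
  cuts <- sort(unique(c(lo[keep], hi[keep])))
  mids <- (head(cuts, -1) + tail(cuts, -1)) / 2
  lens <- diff(cuts)
  pri <- vapply(vols, `[[`, integer(1), "priority")
  seg_mat <- character(length(mids))
  seg_mu <- seg_cf <- numeric(length(mids))
  for (i in seq_along(mids)) {
    inside <- which(keep & lo <= mids[i] & hi >= mids[i])
    if (length(inside) == 0L) { seg_mat[i] <- NA_character_; next }
    v <- vols[[inside[which.max(pri[inside])]]]
    seg_mat[i] <- v$material$name
    seg_mu[i] <- v$material$mu_511
    seg_cf[i] <- v$material$compton_fraction
  }
  ok <- !is.na(seg_mat)
  out <- tibble(material = seg_mat[ok], mu_511 = seg_mu[ok],
                compton_fraction = seg_cf[ok], pathlength = lens[ok])
  # merge adjacent segments of the same material
  if (nrow(out) > 1L) {
    grp <- cumsum(c(TRUE, out$material[-1] != out$material[-nrow(out)]))
    out <- out |>
      mutate(.grp = grp) |>
      group_by(.data$.grp) |>
      summarise(material = .data$material[1], mu_511 = .data$mu_511[1],
                compton_fraction = .data$compton_fraction[1],
                pathlength = sum(.data$pathlength), .groups = "drop") |>
      select(-".grp")
  }
  out
}

#' Beer-Lambert survival probability along a segmented path
#'
#' @param segments A data frame with columns `mu_511` (1/cm) and
#'   `pathlength` (cm), as returned by [trace_path()].
#' @return The unscattered survival probability
#'   `exp(-sum(mu_511 * pathlength))`, in `[0, 1]`.
#' @examples
#' attenuation_factor(tibble::tibble(mu_511 = 0.0958, pathlength = 8))
#' @export
attenuation_factor <- function(segments) {
  stopifnot(is.data.frame(segments))
  if (nrow(segments) == 0L) return(1.0)
  if (!all(c("mu_511", "pathlength") %in% names(segments))) {
    stop("`segments` needs columns `mu_511` and `pathlength`", call. = FALSE)
  }
  if (any(segments$pathlength < 0)) {
    stop("negative pathlength", call. = FALSE)
  }
  exp(-sum(segments$mu_511 * segments$pathlength))
}
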