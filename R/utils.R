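# internal helpers shared across modules

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                               allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop(sprintf("`%s` = %g is outside its valid range", name, x),
         call. = FALSE)
  }
  invisible(x)
}

# recursive list merge: values in `new` override `base`
.deep_merge <- function(base, new) {
  if (is.null(new)) return(base)
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) && !is.null(names(new[[nm]]))) {
      base[[nm]] <- .deep_merge(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

.normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero direction vector", call. = FALSE)
  m / nrm
}

.normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero direction vector", call. = FALSE)
  v / n
}

# uniform directions on the unit sphere, as an n x 3 matrix
.sphere_directions <- function(n) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

# derive a stream of distinct 31-bit seeds from one user seed
.derive_seeds <- function(seed, n) {
  (as.integer(seed) + 7919L * seq_len(n)) %% .Machine$integer.max
}
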