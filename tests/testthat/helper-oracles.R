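# Brute-force oracles, independent of the package's rendering code.

# render a single 2D Gaussian w * exp(-(x^2+y^2) / (2 s^2)) on the grid
oracle_gaussian_iso <- function(w, s, half) {
  off <- seq(-half, half)
  x <- matrix(off, length(off), length(off), byrow = TRUE)
  y <- matrix(off, length(off), length(off))
  w * exp(-(x^2 + y^2) / (2 * s^2))
}

# anisotropic Gaussian evaluated on explicitly rotated coordinates:
# the filter rotated by alpha means sampling the axis-aligned Gaussian at
# (x', y') = (x cos a - y sin a, x sin a + y cos a)
oracle_gaussian_aniso <- function(w, sx, sy, alpha, half) {
  off <- seq(-half, half)
  x <- matrix(off, length(off), length(off), byrow = TRUE)
  y <- matrix(off, length(off), length(off))
  xr <- x * cos(alpha) - y * sin(alpha)
  yr <- x * sin(alpha) + y * cos(alpha)
  w * exp(-xr^2 / (2 * sx^2) - yr^2 / (2 * sy^2))
}

# plain O(n^2 k^2) zero-padded cross-correlation in R
oracle_conv2 <- function(X, K) {
  h <- (nrow(K) - 1) / 2
  nr <- nrow(X); nc <- ncol(X)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (u in -h:h) for (v in -h:h) {
      ii <- i + u; jj <- j + v
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc)
        s <- s + K[u + h + 1, v + h + 1] * X[ii, jj]
    }
    out[i, j] <- s
  }
  out
}

# maximum-cardinality matching by exhaustive recursion (<= 6 points)
oracle_max_matching <- function(dx, dy, tx, ty, rho) {
  nd <- length(dx); nt <- length(tx)
  if (nd == 0 || nt == 0) return(0L)
  ok <- outer(dx, tx, `-`)^2 + outer(dy, ty, `-`)^2 < rho^2
  best <- 0L
  rec <- function(i, used, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    rec(i + 1, used, count)                      # leave detection i out
    for (t in seq_len(nt)) {
      if (!used[t] && ok[i, t]) {
        used[t] <- TRUE
        rec(i + 1, used, count + 1L)
        used[t] <- FALSE
      }
    }
  }
  rec(1L, logical(nt), 0L)
  best
}

# finite-difference gradient of a scalar function of a named vector
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# small scene used across tests
tiny_scene <- function(seed = 1, size = 48, snr = 20) {
  generate_scene(synthetic_config(size = size, n_excitatory = 5,
                                  n_spurious = 2, snr = snr,
                                  max_displacement = 1, seed = seed))
}
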