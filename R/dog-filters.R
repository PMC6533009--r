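#' @useDynLib dognet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Difference-of-Gaussians filter kernels.
##
## Five parameterizations are supported, named by their trainable degrees of
## freedom:
##   isotropic-2    sigma1, sigma2                (normalized amplitudes)
##   isotropic-4    w1, w2, sigma1, sigma2
##   anisotropic-5  sigma1x, sigma1y, sigma2x, sigma2y, alpha  (normalized)
##   anisotropic-7  w1, w2, sigma1x, sigma1y, sigma2x, sigma2y, alpha
##   dog3d-6        w1, w2, sigma1, sigma2, sigma1z, sigma2z
## Normalized variants fix each amplitude at the 2D Gaussian pdf normalizer
## so that the kernel integrates to ~0 (pure band-pass).

.dog_kinds <- c("isotropic-2", "isotropic-4", "anisotropic-5",
                "anisotropic-7", "dog3d-6")

.dog_param_names <- function(kind) {
  switch(kind,
    "isotropic-2"   = c("sigma1", "sigma2"),
    "isotropic-4"   = c("w1", "w2", "sigma1", "sigma2"),
    "anisotropic-5" = c("sigma1x", "sigma1y", "sigma2x", "sigma2y", "alpha"),
    "anisotropic-7" = c("w1", "w2", "sigma1x", "sigma1y", "sigma2x", "sigma2y",
                        "alpha"),
    "dog3d-6"       = c("w1", "w2", "sigma1", "sigma2", "sigma1z", "sigma2z"),
    stop("unknown DoG kind: ", kind))
}

.check_sigmas <- function(p) {
  s <- p[grepl("^sigma", names(p))]
  if (any(!is.finite(s)) || any(s <= 0))
    stop("all sigma parameters must be positive and finite", call. = FALSE)
}

#' DoG filter parameter vectors
#'
#' Construct a named parameter vector for one Difference-of-Gaussians filter.
#' Amplitudes `w1`, `w2` are only present in the explicit-amplitude variants;
#' the normalized variants derive them from the sigmas via
#' [normalizing_amplitude()].
#'
#' @param sigma1,sigma2 Bandwidths (standard deviations) of the inner and
#'   outer Gaussian, in pixels.
#' @param w1,w2 Amplitudes of the two Gaussians (dimensionless).
#' @param kind One of `"isotropic-2"`, `"isotropic-4"`, `"anisotropic-5"`,
#'   `"anisotropic-7"`, `"dog3d-6"`.
#' @param sigma1x,sigma1y,sigma2x,sigma2y Per-axis bandwidths of the two
#'   anisotropic Gaussians, in pixels, before rotation.
#' @param alpha Shared orientation angle in radians; reduced modulo pi.
#' @param sigma1z,sigma2z Axial bandwidths in slices (3D variant).
#' @return A `dog_params` object: a named numeric vector with a `kind`
#'   attribute.
#' @export
dog_params <- function(kind, sigma1 = NULL, sigma2 = NULL, w1 = NULL,
                       w2 = NULL, sigma1x = NULL, sigma1y = NULL,
                       sigma2x = NULL, sigma2y = NULL, alpha = NULL,
                       sigma1z = NULL, sigma2z = NULL) {
  kind <- match.arg(kind, .dog_kinds)
  vals <- c(sigma1 = sigma1, sigma2 = sigma2, w1 = w1, w2 = w2,
            sigma1x = sigma1x, sigma1y = sigma1y, sigma2x = sigma2x,
            sigma2y = sigma2y, alpha = alpha, sigma1z = sigma1z,
            sigma2z = sigma2z)
  need <- .dog_param_names(kind)
  if (!all(need %in% names(vals)))
    stop("kind '", kind, "' requires parameters: ",
         paste(setdiff(need, names(vals)), collapse = ", "))
  p <- vals[need]
  if ("alpha" %in% need) p["alpha"] <- p["alpha"] %% pi
  .check_sigmas(p)
  structure(p, kind = kind, class = "dog_params")
}

#' Kernel support grid
#'
#' The discrete sampling window of a rendered kernel: integer pixel offsets
#' centered at 0.  The default 15 x 15 window (half-width 7) matches the
#' receptive field used throughout the package.
#'
#' @param size Window side in pixels; must be odd.
#' @param z_size Window side along z in slices (3D kernels); must be odd.
#' @return A `kernel_support` list with elements `half`, `offsets`,
#'   `z_half`, `z_offsets`.
#' @export
kernel_support <- function(size = 15, z_size = 5) {
  if (size %% 2 != 1 || size < 1) stop("support size must be odd and >= 1")
  if (z_size %% 2 != 1 || z_size < 1) stop("z support size must be odd and >= 1")
  half <- (size - 1L) / 2L
  z_half <- (z_size - 1L) / 2L
  structure(list(half = half, offsets = seq.int(-half, half),
                 z_half = z_half, z_offsets = seq.int(-z_half, z_half)),
            class = "kernel_support")
}

#' Normalizing amplitudes of a DoG filter
#'
#' For the normalized variants the amplitudes are fixed at the 2D Gaussian
#' probability-density normalizer: `1 / (2 * pi * sigma_i^2)` for isotropic
#' filters and `1 / (2 * pi * sigma_ix * sigma_iy)` for anisotropic filters,
#' so each Gaussian term integrates to one and their difference is a
#' zero-DC band-pass kernel.
#'
#' @param params A [dog_params()] vector (any kind).
#' @return Numeric vector `c(w1, w2)`.
#' @export
normalizing_amplitude <- function(params) {
  kind <- attr(params, "kind")
  .check_sigmas(params)
  p <- as.list(unclass(params))
  switch(kind,
    "isotropic-2" = ,
    "isotropic-4" = c(w1 = 1 / (2 * pi * p$sigma1^2),
                      w2 = 1 / (2 * pi * p$sigma2^2)),
    "anisotropic-5" = ,
    "anisotropic-7" = c(w1 = 1 / (2 * pi * p$sigma1x * p$sigma1y),
                        w2 = 1 / (2 * pi * p$sigma2x * p$sigma2y)),
    "dog3d-6" = c(w1 = 1 / (2 * pi * p$sigma1^2),
                  w2 = 1 / (2 * pi * p$sigma2^2)))
}

## Quadratic-form coefficients of a rotated anisotropic Gaussian
## exp(-a x^2 - 2 b x y - c y^2); alpha measured from the +x axis.
.aniso_abc <- function(sx, sy, alpha) {
  ca2 <- cos(alpha)^2; sa2 <- sin(alpha)^2; s2a <- sin(2 * alpha)
  list(a = ca2 / (2 * sx^2) + sa2 / (2 * sy^2),
       b = -s2a / (4 * sx^2) + s2a / (4 * sy^2),
       c = sa2 / (2 * sx^2) + ca2 / (2 * sy^2))
}

## x = column offset, y = row offset on the support grid.
.grid_xy <- function(support) {
  off <- support$offsets
  n <- length(off)
  list(x = matrix(off, n, n, byrow = TRUE), y = matrix(off, n, n))
}

#' Render a DoG kernel on a discrete support
#'
#' Evaluates the continuous filter formula at the integer pixel offsets of
#' the support grid (no supersampling).  2D kinds return a matrix indexed
#' `[row, column]` with `x` along columns and `y` along rows; `"dog3d-6"`
#' returns a 3D array with the third index along z.
#'
#' @param params A [dog_params()] vector.
#' @param support A [kernel_support()].
#' @return Numeric matrix (2D kinds) or array (3D kind).
#' @export
dog_kernel <- function(params, support = kernel_support()) {
  .check_sigmas(params)
  kind <- attr(params, "kind")
  p <- as.list(unclass(params))
  g <- .grid_xy(support)
  if (kind %in% c("isotropic-2", "isotropic-4")) {
    w <- if (kind == "isotropic-2") normalizing_amplitude(params) else
      c(p$w1, p$w2)
    r2 <- g$x^2 + g$y^2
    w[1] * exp(-r2 / (2 * p$sigma1^2)) - w[2] * exp(-r2 / (2 * p$sigma2^2))
  } else if (kind %in% c("anisotropic-5", "anisotropic-7")) {
    w <- if (kind == "anisotropic-5") normalizing_amplitude(params) else
      c(p$w1, p$w2)
    q1 <- .aniso_abc(p$sigma1x, p$sigma1y, p$alpha)
    q2 <- .aniso_abc(p$sigma2x, p$sigma2y, p$alpha)
    w[1] * exp(-q1$a * g$x^2 - 2 * q1$b * g$x * g$y - q1$c * g$y^2) -
      w[2] * exp(-q2$a * g$x^2 - 2 * q2$b * g$x * g$y - q2$c * g$y^2)
  } else { # dog3d-6
    r2 <- g$x^2 + g$y^2
    zo <- support$z_offsets
    k <- vapply(zo, function(z) {
      p$w1 * exp(-r2 / (2 * p$sigma1^2) - z^2 / (2 * p$sigma1z^2)) -
        p$w2 * exp(-r2 / (2 * p$sigma2^2) - z^2 / (2 * p$sigma2z^2))
    }, matrix(0, length(support$offsets), length(support$offsets)))
    k
  }
}

#' Analytic parameter gradients of a rendered DoG kernel
#'
#' Returns, for each trainable parameter of the filter, the kernel-shaped
#' array of partial derivatives of every kernel entry with respect to that
#' parameter.  These are the exact derivatives of the rendering formulas and
#' drive gradient-based training.
#'
#' @inheritParams dog_kernel
#' @return Named list of matrices/arrays, one per parameter, in the order of
#'   `names(params)`.
#' @export
dog_kernel_grad <- function(params, support = kernel_support()) {
  .check_sigmas(params)
  kind <- attr(params, "kind")
  p <- as.list(unclass(params))
  g <- .grid_xy(support)
  out <- switch(kind,
    "isotropic-2" = {
      r2 <- g$x^2 + g$y^2
      t1 <- exp(-r2 / (2 * p$sigma1^2)) / (2 * pi * p$sigma1^2)
      t2 <- exp(-r2 / (2 * p$sigma2^2)) / (2 * pi * p$sigma2^2)
      list(sigma1 = t1 * (r2 / p$sigma1^3 - 2 / p$sigma1),
           sigma2 = -t2 * (r2 / p$sigma2^3 - 2 / p$sigma2))
    },
    "isotropic-4" = {
      r2 <- g$x^2 + g$y^2
      e1 <- exp(-r2 / (2 * p$sigma1^2))
      e2 <- exp(-r2 / (2 * p$sigma2^2))
      list(w1 = e1, w2 = -e2,
           sigma1 = p$w1 * e1 * r2 / p$sigma1^3,
           sigma2 = -p$w2 * e2 * r2 / p$sigma2^3)
    },
    "anisotropic-5" = ,
    "anisotropic-7" = {
      normalized <- kind == "anisotropic-5"
      w <- if (normalized) normalizing_amplitude(params) else c(p$w1, p$w2)
      q1 <- .aniso_abc(p$sigma1x, p$sigma1y, p$alpha)
      q2 <- .aniso_abc(p$sigma2x, p$sigma2y, p$alpha)
      G1 <- w[1] * exp(-q1$a * g$x^2 - 2 * q1$b * g$x * g$y - q1$c * g$y^2)
      G2 <- w[2] * exp(-q2$a * g$x^2 - 2 * q2$b * g$x * g$y - q2$c * g$y^2)
      ca2 <- cos(p$alpha)^2; sa2 <- sin(p$alpha)^2
      s2a <- sin(2 * p$alpha); c2a <- cos(2 * p$alpha)
      ## exponent derivative wrt sigma_x of one Gaussian
      dexp_sx <- function(G, sx) {
        da <- -ca2 / sx^3; db <- s2a / (2 * sx^3); dc <- -sa2 / sx^3
        G * (-g$x^2 * da - 2 * g$x * g$y * db - g$y^2 * dc)
      }
      dexp_sy <- function(G, sy) {
        da <- -sa2 / sy^3; db <- -s2a / (2 * sy^3); dc <- -ca2 / sy^3
        G * (-g$x^2 * da - 2 * g$x * g$y * db - g$y^2 * dc)
      }
      dalpha <- function(G, sx, sy) {
        d <- 1 / sy^2 - 1 / sx^2
        da <- s2a / 2 * d; db <- c2a / 2 * d; dc <- -s2a / 2 * d
        G * (-g$x^2 * da - 2 * g$x * g$y * db - g$y^2 * dc)
      }
      ds1x <- dexp_sx(G1, p$sigma1x); ds1y <- dexp_sy(G1, p$sigma1y)
      ds2x <- -dexp_sx(G2, p$sigma2x); ds2y <- -dexp_sy(G2, p$sigma2y)
      if (normalized) { # amplitude also depends on the sigmas
        ds1x <- ds1x - G1 / p$sigma1x; ds1y <- ds1y - G1 / p$sigma1y
        ds2x <- ds2x + G2 / p$sigma2x; ds2y <- ds2y + G2 / p$sigma2y
      }
      res <- list(sigma1x = ds1x, sigma1y = ds1y, sigma2x = ds2x,
                  sigma2y = ds2y,
                  alpha = dalpha(G1, p$sigma1x, p$sigma1y) -
                    dalpha(G2, p$sigma2x, p$sigma2y))
      if (!normalized)
        res <- c(list(w1 = G1 / p$w1, w2 = -G2 / p$w2), res)
      res
    },
    "dog3d-6" = {
      r2 <- g$x^2 + g$y^2
      zo <- support$z_offsets
      n <- length(support$offsets)
      shape <- function(f) vapply(zo, f, matrix(0, n, n))
      e1 <- shape(function(z) exp(-r2 / (2 * p$sigma1^2) - z^2 / (2 * p$sigma1z^2)))
      e2 <- shape(function(z) exp(-r2 / (2 * p$sigma2^2) - z^2 / (2 * p$sigma2z^2)))
      z2 <- shape(function(z) matrix(z^2, n, n))
      list(w1 = e1, w2 = -e2,
           sigma1 = p$w1 * e1 * c(r2) / p$sigma1^3,
           sigma2 = -p$w2 * e2 * c(r2) / p$sigma2^3,
           sigma1z = p$w1 * e1 * z2 / p$sigma1z^3,
           sigma2z = -p$w2 * e2 * z2 / p$sigma2z^3)
    })
  out[names(params)]
}
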