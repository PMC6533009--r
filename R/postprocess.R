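## Post-processing: probability map -> synapse detections -> per-channel
## Gaussian punctum descriptors.

#' Threshold a probability map
#'
#' Pixels below `tau` are set to 0; values at or above `tau` are preserved.
#'
#' @param map Matrix with values in \[0, 1\].
#' @param tau Confidence threshold in \[0, 1\] (default 0.5).
#' @return Matrix of the same shape.
#' @export
threshold_map <- function(map, tau = 0.5) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  map[map < tau] <- 0
  map
}

#' Non-maximum suppression on a thresholded map
#'
#' Local maxima (8-neighborhood; the first pixel of a plateau in row-major
#' order represents the plateau) are visited in decreasing value order,
#' ties broken by row-major position, and accepted greedily unless a
#' previously accepted detection lies within the cut-off radius `R`.
#'
#' @param map Thresholded probability map (zeros suppressed).
#' @param R Suppression radius in micrometers (default 1.6).
#' @param pixel_size Micrometers per pixel.
#' @return Data frame of detections: `x`, `y` (0-based pixel coordinates),
#'   `x_um`, `y_um`, `confidence`; sorted by decreasing confidence.
#' @export
nonmax_suppression <- function(map, R = 1.6, pixel_size = 0.2) {
  peaks <- .local_maxima(map)
  empty <- data.frame(x = numeric(), y = numeric(), x_um = numeric(),
                      y_um = numeric(), confidence = numeric())
  if (nrow(peaks) == 0) return(empty)
  ## decreasing value; ties in row-major (x, then y) order
  ord <- order(-peaks$value, peaks$y, peaks$x)
  peaks <- peaks[ord, ]
  r_px2 <- (R / pixel_size)^2
  keep_x <- numeric(); keep_y <- numeric(); keep_v <- numeric()
  for (i in seq_len(nrow(peaks))) {
    px <- peaks$x[i]; py <- peaks$y[i]
    if (length(keep_x) == 0 ||
        all((keep_x - px)^2 + (keep_y - py)^2 >= r_px2)) {
      keep_x <- c(keep_x, px); keep_y <- c(keep_y, py)
      keep_v <- c(keep_v, peaks$value[i])
    }
  }
  data.frame(x = keep_x, y = keep_y, x_um = keep_x * pixel_size,
             y_um = keep_y * pixel_size, confidence = keep_v)
}

## strict-or-plateau local maxima of a nonnegative map; returns 0-based x, y
.local_maxima <- function(map) {
  nr <- nrow(map); nc <- ncol(map)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- map
  ge_all <- matrix(TRUE, nr, nc)
  strict_any <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    ge_all <- ge_all & (map >= nb)
    strict_any <- strict_any | (map > nb)
  }
  cand <- which(ge_all & map > 0)
  if (!length(cand))
    return(data.frame(x = numeric(), y = numeric(), value = numeric()))
  rows <- (cand - 1) %% nr + 1
  cols <- (cand - 1) %/% nr + 1
  val <- map[cand]
  ## plateau handling: among connected equal-valued candidates keep the
  ## first in row-major order (scan rows within columns of the transpose:
  ## row-major = increasing y, then x); a simple dedup by suppressing any
  ## candidate with an equal-valued candidate neighbor earlier in
  ## row-major order
  keep <- rep(TRUE, length(cand))
  rm_order <- order(rows, cols)  # row-major: y then x
  pos <- matrix(0L, nr, nc)
  for (idx in seq_along(rm_order)) pos[cand[rm_order[idx]]] <- idx
  for (i in seq_along(cand)) {
    r <- rows[i]; cc <- cols[i]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
      j <- pos[rr, ccc]
      if (j > 0 && map[rr, ccc] == val[i] &&
          j < pos[r, cc]) keep[i] <- FALSE
    }
  }
  data.frame(x = cols[keep] - 1, y = rows[keep] - 1, value = val[keep])
}

#' Fit a Gaussian punctum descriptor in each channel
#'
#' Around a detection, a window of radius `R` is cut from every input
#' channel and a 2D anisotropic Gaussian (amplitude, offset, mean,
#' covariance) is least-squares fitted (Levenberg-Marquardt with
#' moment-based initialization).  The descriptor per channel holds the
#' window mean intensity, the displacement of the fitted mean from the
#' window center in micrometers, the principal-axis orientation in radians
#' and the asymmetry as the major/minor axis ratio (>= 1).  Flat windows
#' yield a descriptor flagged `degenerate` with displacement 0 and
#' asymmetry 1.
#'
#' @param channels 3D array `[row, col, channel]` or [channel_stack()].
#' @param center A single detection: list/row with `x`, `y` in 0-based
#'   pixels.
#' @param R Window radius in micrometers (default 1.6).
#' @param pixel_size Micrometers per pixel.
#' @param max_iter Iteration cap of the nonlinear fit (default 100).
#' @return Data frame with one row per channel: `channel`, `mean_intensity`,
#'   `dx_um`, `dy_um`, `orientation`, `asymmetry`, `degenerate`, `clipped`.
#' @export
fit_punctum <- function(channels, center, R = 1.6, pixel_size = 0.2,
                        max_iter = 100) {
  labels <- if (inherits(channels, "channel_stack")) channels$channels else NULL
  channels <- .as_stack_array(channels)
  nr <- dim(channels)[1]; nc <- dim(channels)[2]; nch <- dim(channels)[3]
  if (is.null(labels)) labels <- paste0("ch", seq_len(nch) - 1)
  r_px <- round(R / pixel_size)
  crow <- round(center$y) + 1; ccol <- round(center$x) + 1
  rows <- max(1, crow - r_px):min(nr, crow + r_px)
  cols <- max(1, ccol - r_px):min(nc, ccol + r_px)
  clipped <- length(rows) < 2 * r_px + 1 || length(cols) < 2 * r_px + 1
  out <- vector("list", nch)
  for (ch in seq_len(nch)) {
    w <- channels[rows, cols, ch]
    fit <- .fit_gauss2d(w, crow - rows[1] + 1, ccol - cols[1] + 1, max_iter)
    out[[ch]] <- data.frame(
      channel = labels[ch],
      mean_intensity = mean(w),
      dx_um = fit$dx * pixel_size,
      dy_um = fit$dy * pixel_size,
      orientation = fit$orientation,
      asymmetry = fit$asymmetry,
      degenerate = fit$degenerate,
      clipped = clipped)
  }
  do.call(rbind, out)
}

## least-squares 2D Gaussian fit of a window; (crow, ccol) is the window
## center in 1-based window coordinates
.fit_gauss2d <- function(w, crow, ccol, max_iter = 100) {
  degen <- list(dx = 0, dy = 0, orientation = 0, asymmetry = 1,
                degenerate = TRUE)
  if (stats::sd(w) == 0) return(degen)
  nr <- nrow(w); nc <- ncol(w)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  ## moment initialization on the background-subtracted window
  wp <- pmax(w - min(w), 0)
  tot <- sum(wp)
  if (tot == 0) return(degen)
  mx <- sum(wp * xs) / tot; my <- sum(wp * ys) / tot
  vx <- max(sum(wp * (xs - mx)^2) / tot, 0.25)
  vy <- max(sum(wp * (ys - my)^2) / tot, 0.25)
  cxy <- sum(wp * (xs - mx) * (ys - my)) / tot
  start <- c(A = max(w) - min(w), b = min(w), mx = mx, my = my,
             lsx = log(sqrt(vx)), lsy = log(sqrt(vy)), rho = atanh(
               max(min(cxy / sqrt(vx * vy), 0.9), -0.9)))
  model <- function(p) {
    sx <- exp(p["lsx"]); sy <- exp(p["lsy"]); r <- tanh(p["rho"])
    dx <- xs - p["mx"]; dy <- ys - p["my"]
    q <- (dx^2 / sx^2 - 2 * r * dx * dy / (sx * sy) + dy^2 / sy^2) /
      (2 * (1 - r^2))
    p["A"] * exp(-q) + p["b"]
  }
  ## the iteration cap is intentional; reaching it is not an error
  res <- try(suppressWarnings(minpack.lm::nls.lm(
    par = start, fn = function(p) as.vector(w - model(p)),
    control = minpack.lm::nls.lm.control(maxiter = max_iter))),
    silent = TRUE)
  p <- if (inherits(res, "try-error")) start else res$par
  sx <- exp(p[["lsx"]]); sy <- exp(p[["lsy"]]); r <- tanh(p[["rho"]])
  cov <- matrix(c(sx^2, r * sx * sy, r * sx * sy, sy^2), 2)
  ev <- eigen(cov, symmetric = TRUE)
  ## principal axis in (x, y); orientation from +x axis, modulo pi
  v <- ev$vectors[, 1]
  orientation <- atan2(v[2], v[1]) %% pi
  asym <- sqrt(max(ev$values[1], 1e-12) / max(ev$values[2], 1e-12))
  list(dx = p[["mx"]] - ccol, dy = p[["my"]] - crow,
       orientation = orientation, asymmetry = max(asym, 1),
       degenerate = FALSE)
}

#' Detect synapses in a probability map
#'
#' Full post-processing chain: [threshold_map()] at `tau`,
#' [nonmax_suppression()] at radius `R`, centroid localization
#' refinement, and per-detection [fit_punctum()] descriptors when the
#' underlying channels are supplied.
#'
#' Soft-Dice-trained maps reproduce the flat-topped training disks, so
#' the raw argmax of a blob wanders with noise; each accepted peak is
#' therefore moved to the centroid of the thresholded map within
#' `refine_radius` (the annotation disk radius), which estimates the blob
#' center far more stably.  Set `refine_radius = 0` for raw peak
#' positions.
#'
#' @param map Probability map matrix in \[0, 1\].
#' @param tau Confidence threshold (default 0.5).
#' @param R NMS/descriptor radius in micrometers (default 1.6).
#' @param pixel_size Micrometers per pixel.
#' @param channels Optional channel stack for descriptors.
#' @param refine_radius Localization refinement radius in micrometers
#'   (default 0.8, the mask disk radius).
#' @return Detection data frame; with `channels`, per-channel descriptor
#'   columns `<label>.mean_intensity`, `<label>.dx_um`, ... are appended.
#' @export
detect_synapses <- function(map, tau = 0.5, R = 1.6, pixel_size = 0.2,
                            channels = NULL, refine_radius = 0.8) {
  tm <- threshold_map(map, tau)
  dets <- nonmax_suppression(tm, R, pixel_size)
  if (refine_radius > 0 && nrow(dets) > 0) {
    rad <- round(refine_radius / pixel_size)
    for (i in seq_len(nrow(dets))) {
      r0 <- round(dets$y[i]) + 1; c0 <- round(dets$x[i]) + 1
      rows <- max(1, r0 - rad):min(nrow(map), r0 + rad)
      cols <- max(1, c0 - rad):min(ncol(map), c0 + rad)
      w <- tm[rows, cols]
      if (sum(w) > 0) {
        dets$y[i] <- sum(w * (rows - 1)) / sum(w)
        dets$x[i] <- sum(t(w) * (cols - 1)) / sum(w)
      }
    }
    dets$x_um <- dets$x * pixel_size
    dets$y_um <- dets$y * pixel_size
  }
  if (!is.null(channels) && nrow(dets) > 0) {
    desc <- lapply(seq_len(nrow(dets)), function(i) {
      d <- fit_punctum(channels, dets[i, ], R, pixel_size)
      vals <- unlist(lapply(seq_len(nrow(d)), function(j)
        stats::setNames(
          as.numeric(d[j, c("mean_intensity", "dx_um", "dy_um",
                            "orientation", "asymmetry")]),
          paste(d$channel[j], c("mean_intensity", "dx_um", "dy_um",
                                "orientation", "asymmetry"), sep = "."))))
      vals
    })
    dets <- cbind(dets, do.call(rbind, desc))
  }
  dets
}
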