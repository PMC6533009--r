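## Training: point annotations -> disk masks, soft-Dice loss, random
## patch sampling, and gradient descent on the DoG parameters.

.SIGMA_FLOOR <- 0.05

#' Rasterize point annotations into a binary mask
#'
#' Every pixel whose center lies within `radius` (in micrometers) of any
#' annotated centroid is set to 1; overlapping disks union.  Annotations
#' outside the image contribute their clipped disk with a warning.
#'
#' @param annotations Data frame with columns `x`, `y` (0-based pixel
#'   coordinates, x along columns) or micrometer coordinates when a `unit`
#'   column says `"um"`.
#' @param shape Integer vector `c(rows, cols)`.
#' @param radius Disk radius in micrometers (default 0.8).
#' @param pixel_size Pixel size in micrometers per pixel.
#' @return Binary matrix of dimension `shape`.
#' @export
rasterize_mask <- function(annotations, shape, radius = 0.8,
                           pixel_size = 0.2) {
  mask <- matrix(0, shape[1], shape[2])
  if (is.null(annotations) || nrow(annotations) == 0) return(mask)
  xy <- .annotations_px(annotations, pixel_size)
  r_px <- radius / pixel_size
  for (i in seq_len(nrow(xy))) {
    cx <- xy$x[i]; cy <- xy$y[i]
    if (cx < 0 || cy < 0 || cx > shape[2] - 1 || cy > shape[1] - 1)
      warning("annotation ", i, " lies outside the image; disk clipped")
    cols <- max(1, ceiling(cx - r_px) + 1):min(shape[2], floor(cx + r_px) + 1)
    rows <- max(1, ceiling(cy - r_px) + 1):min(shape[1], floor(cy + r_px) + 1)
    if (!length(cols) || !length(rows)) next
    dx2 <- (cols - 1 - cx)^2
    dy2 <- (rows - 1 - cy)^2
    hit <- outer(dy2, dx2, `+`) <= r_px^2
    mask[rows, cols][hit] <- 1
  }
  mask
}

## annotation coordinates in pixels, honoring an optional unit column
.annotations_px <- function(annotations, pixel_size) {
  x <- annotations$x; y <- annotations$y
  if (!is.null(annotations$unit)) {
    um <- annotations$unit == "um"
    x[um] <- x[um] / pixel_size
    y[um] <- y[um] / pixel_size
  }
  data.frame(x = x, y = y)
}

#' Soft-Dice loss
#'
#' `1 - 2 * sum(target * pred) / (sum(pred^2) + sum(target^2))`, a
#' differentiable relaxation of one minus the Dice overlap, robust to the
#' extreme class imbalance of puncta masks.  A small epsilon in the
#' denominator makes the all-zero/all-zero case evaluate to 0.
#'
#' @param pred Matrix of predicted probabilities in \[0,1\].
#' @param target Binary matrix of the same shape.
#' @param eps Guard added to numerator and denominator (default 1e-8), so
#'   an all-zero prediction against an all-zero target scores 0.
#' @return Scalar loss in \[0, 1\].
#' @export
softdice_loss <- function(pred, target, eps = 1e-8) {
  if (!identical(dim(pred), dim(target))) stop("pred/target shapes differ")
  1 - (2 * sum(target * pred) + eps) /
    (sum(pred^2) + sum(target^2) + eps)
}

.softdice_grad <- function(pred, target, eps = 1e-8) {
  A2 <- 2 * sum(target * pred) + eps
  B <- sum(pred^2) + sum(target^2) + eps
  (-2 * target * B + 2 * A2 * pred) / B^2
}

#' Sample aligned training patches
#'
#' Draws `n` axis-aligned square crops at uniformly random valid offsets,
#' always fully inside the image, using the current R random number
#' generator state (seed it for reproducibility).
#'
#' @param image 3D array `[row, col, channel]` (or matrix).
#' @param mask Binary matrix matching the image's spatial size.
#' @param n Number of patches.
#' @param side Patch side in pixels (default 64).
#' @return List of `list(x = patch array, y = mask patch)` pairs.
#' @export
sample_patches <- function(image, mask, n = 10, side = 64) {
  image <- .as_stack_array(image)
  nr <- dim(image)[1]; nc <- dim(image)[2]
  if (side > nr || side > nc)
    stop("patch side ", side, " exceeds image size ", nr, " x ", nc,
         "; need an image of at least ", side, " x ", side)
  r0 <- sample.int(nr - side + 1L, n, replace = TRUE)
  c0 <- sample.int(nc - side + 1L, n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    rows <- r0[i]:(r0[i] + side - 1L); cols <- c0[i]:(c0[i] + side - 1L)
    list(x = image[rows, cols, , drop = FALSE], y = mask[rows, cols])
  })
}

## ---- backpropagation ----

## Gradient of softdice(forward(x), target) w.r.t. every natural-scale
## parameter, returned as a params-shaped list plus the loss.
dognet_backward <- function(x, target, params, config) {
  fw <- dognet_forward(x, params, config, cache = TRUE)
  P <- fw$map
  loss <- softdice_loss(P, target)
  dP <- .softdice_grad(P, target)
  Tn <- length(config$layers)
  final <- fw$layers[[Tn]]$maps
  dY <- if (config$use_product) {
    lapply(seq_along(final), function(k) {
      others <- final[-k]
      dP * if (length(others)) Reduce(`*`, others) else 1
    })
  } else list(dP)
  grads <- vector("list", Tn)
  for (t in Tn:1) {
    lc <- config$layers[[t]]
    cache <- fw$layers[[t]]
    bk <- .layer_backward(dY, cache, params[[t]], lc, config$support,
                          need_dx = t > 1)
    grads[[t]] <- bk$grad
    if (t > 1) dY <- bk$dx
  }
  list(loss = loss, grad = grads)
}

.layer_backward <- function(dY, cache, lp, lc, support, need_dx) {
  M <- lc$filters_per_channel; N <- lc$n_in; K <- lc$n_out
  dS <- lapply(seq_len(K), function(k) {
    Y <- cache$maps[[k]]
    dY[[k]] * Y * (1 - Y)
  })
  dzeta <- vapply(dS, sum, 0)
  dgamma <- array(0, c(K, M, N))
  dresp <- vector("list", M * N)
  for (n in seq_len(N)) for (m in seq_len(M)) {
    i <- (n - 1) * M + m
    dr <- 0
    for (k in seq_len(K)) {
      dgamma[k, m, n] <- sum(dS[[k]] * cache$resp[[i]])
      dr <- dr + lp$gamma[k, m, n] * dS[[k]]
    }
    dresp[[i]] <- dr
  }
  h <- support$half
  dbeta <- vector("list", N)
  for (n in seq_len(N)) {
    dbeta[[n]] <- vector("list", M)
    for (m in seq_len(M)) {
      i <- (n - 1) * M + m
      Gk <- conv2_kernel_grad(cache$x[, , n], dresp[[i]], h, h)
      dkdp <- dog_kernel_grad(lp$beta[[n]][[m]], support)
      g <- vapply(dkdp, function(D) sum(Gk * D), 0)
      dbeta[[n]][[m]] <- g
    }
  }
  out <- list(grad = list(beta = dbeta, gamma = dgamma, zeta = dzeta))
  if (need_dx) {
    nr <- dim(cache$x)[1]; nc <- dim(cache$x)[2]
    dx <- vector("list", N)
    for (n in seq_len(N)) {
      acc <- matrix(0, nr, nc)
      for (m in seq_len(M)) {
        i <- (n - 1) * M + m
        Kf <- cache$kernels[[i]]
        acc <- acc + conv2_same(dresp[[i]], Kf[rev(seq_len(nrow(Kf))),
                                               rev(seq_len(ncol(Kf)))])
      }
      dx[[n]] <- acc
    }
    out$dx <- dx
  }
  out
}

## flatten a grads-shaped list with the same naming as flatten_params
.flatten_grads <- function(grads) {
  flatten_params(structure(grads, class = "dognet_params"))
}

## ---- sigma reparameterization (positivity under gradient steps) ----

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

.is_sigma_name <- function(nm) grepl("\\.sigma", nm)

.to_raw <- function(flat) {
  s <- .is_sigma_name(names(flat))
  flat[s] <- .softplus_inv(pmax(flat[s] - .SIGMA_FLOOR, 1e-12))
  flat
}

.from_raw <- function(raw) {
  s <- .is_sigma_name(names(raw))
  raw[s] <- .SIGMA_FLOOR + .softplus(raw[s])
  raw
}

.raw_chain <- function(raw) {
  d <- rep(1, length(raw))
  s <- .is_sigma_name(names(raw))
  d[s] <- stats::plogis(raw[s])
  d
}

#' Training control parameters
#'
#' @param epochs Number of epochs (default 5000); each epoch processes
#'   `patches_per_epoch` random crops.
#' @param patches_per_epoch Random crops per epoch (default 10).
#' @param patch_size Crop side in pixels (default 64).
#' @param mask_radius Annotation disk radius in micrometers (default 0.8).
#' @param lr Adam learning rate (default 0.01).
#' @param beta1,beta2,adam_eps Adam moment decay rates and epsilon.
#' @param seed RNG seed for initialization and patch sampling.
#' @param normalize Z-score each channel before training/inference.
#' @return A `dognet_control` list.
#' @export
dognet_control <- function(epochs = 5000, patches_per_epoch = 10,
                           patch_size = 64, mask_radius = 0.8, lr = 0.01,
                           beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                           seed = 1, normalize = TRUE) {
  stopifnot(epochs >= 1, patches_per_epoch >= 1, patch_size >= 1, lr >= 0,
            mask_radius > 0)
  structure(list(epochs = epochs, patches_per_epoch = patches_per_epoch,
                 patch_size = patch_size, mask_radius = mask_radius,
                 lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 seed = seed, normalize = normalize),
            class = "dognet_control")
}

#' Fit DoGNet parameters by gradient descent
#'
#' Minimizes the mean soft-Dice loss over randomly cropped patches with
#' Adam; sigmas are optimized through a softplus reparameterization with a
#' floor of 0.05 px so a gradient step can never drive them to zero (which
#' would make the network diverge).
#'
#' @param x Training image: 3D array or [channel_stack()] (already
#'   normalized if desired; [dognet_fit()] handles normalization).
#' @param mask Binary ground-truth mask of the image's spatial size.
#' @param config A [dognet_config()].
#' @param params0 Initial `dognet_params` (default [dognet_init()] with the
#'   control seed).
#' @param control A [dognet_control()].
#' @return List with fitted `params`, per-epoch mean `loss` trace, and the
#'   final flat parameter vector.
#' @export
dognet_train <- function(x, mask, config, params0 = NULL,
                         control = dognet_control()) {
  x <- .as_stack_array(x)
  if (is.null(params0)) params0 <- dognet_init(config, control$seed)
  restore <- .with_preserved_rng(control$seed)
  on.exit(restore())
  side <- min(control$patch_size, dim(x)[1], dim(x)[2])
  flat <- flatten_params(params0)
  raw <- .to_raw(flat)
  mom <- vel <- numeric(length(raw))
  losses <- numeric(control$epochs)
  for (ep in seq_len(control$epochs)) {
    patches <- sample_patches(x, mask, control$patches_per_epoch, side)
    ## identical crops (image == patch) collapse to one evaluation
    if (dim(x)[1] == side && dim(x)[2] == side) patches <- patches[1]
    nat <- .from_raw(raw)
    params <- unflatten_params(nat, config)
    gacc <- numeric(length(raw)); lacc <- 0
    for (pt in patches) {
      bk <- dognet_backward(pt$x, pt$y, params, config)
      gacc <- gacc + .flatten_grads(bk$grad)[names(raw)]
      lacc <- lacc + bk$loss
    }
    np <- length(patches)
    g <- gacc / np
    losses[ep] <- lacc / np
    if (!is.finite(losses[ep]) || any(!is.finite(g))) {
      bad <- names(raw)[!is.finite(g)][1]
      stop("training diverged at epoch ", ep,
           " (non-finite gradient for parameter ",
           if (is.na(bad)) "loss" else bad, ")")
    }
    g <- g * .raw_chain(raw)
    mom <- control$beta1 * mom + (1 - control$beta1) * g
    vel <- control$beta2 * vel + (1 - control$beta2) * g^2
    mh <- mom / (1 - control$beta1^ep)
    vh <- vel / (1 - control$beta2^ep)
    raw <- raw - control$lr * mh / (sqrt(vh) + control$adam_eps)
  }
  final <- .from_raw(raw)
  list(params = unflatten_params(final, config), loss = losses,
       flat = final)
}

#' Z-score image channels
#'
#' Subtracts the mean and divides by the standard deviation of each
#' channel; constant channels are left centered at 0.
#'
#' @param x 3D array `[row, col, channel]` or matrix.
#' @return Array of the same shape.
#' @export
normalize_channels <- function(x) {
  x <- .as_stack_array(x)
  for (ch in seq_len(dim(x)[3])) {
    v <- x[, , ch]
    s <- stats::sd(v)
    x[, , ch] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  }
  x
}
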