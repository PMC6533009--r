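## DoGNet architecture: stacks of DoG-filter layers.
##
## One layer: each of N input channels is convolved with its own M DoG
## filters (depthwise); the M*N response maps are mixed into K output maps
## by a 1x1 convolution (tensor gamma, K x M x N), a bias zeta_k is added
## per map and a sigmoid applied.  Optionally the final K maps are combined
## into one probability map by a parameter-free element-wise product, a
## soft logical AND between presynaptic and postsynaptic evidence.

#' Configuration of one DoGNet layer
#'
#' @param n_in Number of input channels N.
#' @param filters_per_channel Number of DoG filters per channel M.
#' @param n_out Number of output maps K.
#' @param kind DoG parameterization, see [dog_params()].
#' @return A `dognet_layer_config` list.
#' @export
dognet_layer_config <- function(n_in, filters_per_channel = 5, n_out = 2,
                                kind = "isotropic-2") {
  kind <- match.arg(kind, .dog_kinds)
  stopifnot(n_in >= 1, filters_per_channel >= 1, n_out >= 1)
  structure(list(n_in = as.integer(n_in),
                 filters_per_channel = as.integer(filters_per_channel),
                 n_out = as.integer(n_out), kind = kind),
            class = "dognet_layer_config")
}

#' DoGNet architecture configuration
#'
#' A shallow DoGNet is a single layer; a deep DoGNet stacks `depth` layers,
#' each intermediate layer's K maps feeding the next layer as channels.
#' With `use_product = TRUE` the final layer's K maps (K >= 2) are merged by
#' the element-wise product into one probability map.
#'
#' @param n_channels Number of input image channels.
#' @param filters_per_channel Filters per channel M (default 5).
#' @param n_out Output maps per layer K (default 2).
#' @param kind DoG parameterization used by every layer.
#' @param depth Number of stacked layers T (1 = shallow; deep default 3).
#' @param use_product Merge the final K maps by element-wise product.
#' @param support_size Kernel window side in pixels (odd; default 15).
#' @param layers Optionally, an explicit list of [dognet_layer_config()]
#'   objects overriding the homogeneous construction.
#' @return A `dognet_config` object.
#' @examples
#' cfg <- dognet_config(n_channels = 3)          # Shallow Isotropic
#' count_parameters(cfg)                          # 62
#' @export
dognet_config <- function(n_channels, filters_per_channel = 5, n_out = 2,
                          kind = "isotropic-2", depth = 1,
                          use_product = TRUE, support_size = 15,
                          layers = NULL) {
  if (is.null(layers)) {
    kind <- match.arg(kind, .dog_kinds)
    stopifnot(depth >= 1)
    layers <- vector("list", depth)
    n_in <- n_channels
    for (t in seq_len(depth)) {
      layers[[t]] <- dognet_layer_config(n_in, filters_per_channel, n_out,
                                         kind)
      n_in <- n_out
    }
  }
  for (t in seq_along(layers)[-1])
    if (layers[[t]]$n_in != layers[[t - 1]]$n_out)
      stop("layer ", t, " expects ", layers[[t]]$n_in,
           " input channels but layer ", t - 1, " outputs ",
           layers[[t - 1]]$n_out, " maps")
  K_last <- layers[[length(layers)]]$n_out
  if (use_product && K_last < 2)
    stop("the element-wise product layer requires the final K >= 2")
  if (!use_product && K_last != 1)
    stop("without the product layer the final layer must output K = 1 map")
  structure(list(layers = layers, use_product = use_product,
                 support = kernel_support(support_size)),
            class = "dognet_config")
}

#' Count trainable parameters of a DoGNet
#'
#' Per layer: (parameters per filter) * M * N filter parameters, K * M * N
#' mixing weights and K biases.  The element-wise product layer has none.
#'
#' @param config A [dognet_config()].
#' @return Integer total of trainable scalars.
#' @examples
#' count_parameters(dognet_config(3, kind = "isotropic-2"))    # 62
#' count_parameters(dognet_config(3, kind = "anisotropic-5"))  # 107
#' @export
count_parameters <- function(config) {
  per_filter <- c("isotropic-2" = 2L, "isotropic-4" = 4L,
                  "anisotropic-5" = 5L, "anisotropic-7" = 7L, "dog3d-6" = 6L)
  total <- 0L
  for (lc in config$layers) {
    mn <- lc$filters_per_channel * lc$n_in
    total <- total + per_filter[[lc$kind]] * mn + lc$n_out * mn + lc$n_out
  }
  total
}

#' Grid initialization of DoGNet parameters
#'
#' Each channel's M filters start as near-Laplacian-of-Gaussian priors whose
#' first sigmas are the M evenly spaced points spanning \[0.5, 2\] pixels
#' (the midpoint 1.25 when M = 1); the second variance exceeds the first by
#' the difference-variance 0.01, i.e. `sigma2 = sqrt(sigma1^2 + 0.01)`.
#' Anisotropic filters start isotropic with `alpha = 0`; explicit amplitudes
#' start at their normalizing values.  Mixing weights start uniform at
#' random in `±1/sqrt(M*N)` (the standard 1x1-convolution initialization):
#' a symmetric start would give the K maps entering the product layer
#' identical gradients forever, so the presynaptic/postsynaptic AND split
#' could never be learned.  Biases start at 0.
#'
#' @param config A [dognet_config()].
#' @param seed Integer seed; the same seed yields an identical parameter set.
#' @return A `dognet_params` list with one entry per layer, each holding
#'   `beta` (list over channels of lists over filters of [dog_params()]),
#'   `gamma` (K x M x N array) and `zeta` (length-K numeric).
#' @export
dognet_init <- function(config, seed = 1) {
  rng <- .with_preserved_rng(seed)
  on.exit(rng())
  layers <- lapply(config$layers, function(lc) {
    M <- lc$filters_per_channel; N <- lc$n_in; K <- lc$n_out
    s1 <- init_sigma_grid(M)
    s2 <- sqrt(s1^2 + 0.01)
    beta <- lapply(seq_len(N), function(n) {
      lapply(seq_len(M), function(m) .init_filter(lc$kind, s1[m], s2[m]))
    })
    b <- 1 / sqrt(M * N)
    gamma <- array(stats::runif(K * M * N, -b, b), dim = c(K, M, N))
    list(beta = beta, gamma = gamma, zeta = numeric(K))
  })
  structure(layers, class = "dognet_params")
}

#' Evenly spaced initialization sigmas
#'
#' The M first-Gaussian sigmas obtained by splitting the segment \[0.5, 2\]
#' into M - 1 equal parts (endpoints included); M = 1 yields the midpoint.
#'
#' @param m Number of filters per channel.
#' @return Numeric vector of length `m`.
#' @examples
#' init_sigma_grid(3)  # 0.5 1.25 2.0
#' @export
init_sigma_grid <- function(m) {
  stopifnot(m >= 1)
  if (m == 1) 1.25 else seq(0.5, 2, length.out = m)
}

.init_filter <- function(kind, s1, s2) {
  switch(kind,
    "isotropic-2" = dog_params(kind, sigma1 = s1, sigma2 = s2),
    "isotropic-4" = {
      w <- normalizing_amplitude(dog_params("isotropic-2", sigma1 = s1,
                                            sigma2 = s2))
      dog_params(kind, w1 = w[[1]], w2 = w[[2]], sigma1 = s1, sigma2 = s2)
    },
    "anisotropic-5" = dog_params(kind, sigma1x = s1, sigma1y = s1,
                                 sigma2x = s2, sigma2y = s2, alpha = 0),
    "anisotropic-7" = {
      w <- c(1 / (2 * pi * s1^2), 1 / (2 * pi * s2^2))
      dog_params(kind, w1 = w[1], w2 = w[2], sigma1x = s1, sigma1y = s1,
                 sigma2x = s2, sigma2y = s2, alpha = 0)
    },
    "dog3d-6" = {
      w <- c(1 / (2 * pi * s1^2), 1 / (2 * pi * s2^2))
      ## axial resolution is typically lower, start sigma_z at 2 * sigma
      dog_params(kind, w1 = w[1], w2 = w[2], sigma1 = s1, sigma2 = s2,
                 sigma1z = 2 * s1, sigma2z = 2 * s2)
    })
}

## run code under a temporary seed without disturbing the caller's RNG
.with_preserved_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass of one DoGNet layer
#'
#' Convolves each input channel with its M DoG kernels (zero padding,
#' output the size of the input), mixes the M*N response maps into K maps
#' with the gamma weights, adds the biases and applies the sigmoid.
#'
#' @param x 3D array `[row, col, channel]` (or a matrix for N = 1).
#' @param layer_params One layer of a `dognet_params` object.
#' @param layer_config The matching [dognet_layer_config()].
#' @param support The [kernel_support()] to render kernels on.
#' @param cache Keep intermediate maps for backpropagation.
#' @return List of K sigmoid maps (`$maps`); with `cache = TRUE` also the
#'   response maps and pre-sigmoid maps.
#' @export
dognet_layer_forward <- function(x, layer_params, layer_config,
                                 support = kernel_support(), cache = FALSE) {
  if (layer_config$kind == "dog3d-6")
    stop("the 2D forward pass does not support 3D kernels")
  x <- .as_stack_array(x)
  N <- layer_config$n_in; M <- layer_config$filters_per_channel
  K <- layer_config$n_out
  if (dim(x)[3] != N)
    stop("input has ", dim(x)[3], " channels, layer expects ", N)
  kernels <- resp <- vector("list", M * N)
  for (n in seq_len(N)) for (m in seq_len(M)) {
    i <- (n - 1) * M + m
    kernels[[i]] <- dog_kernel(layer_params$beta[[n]][[m]], support)
    resp[[i]] <- conv2_same(x[, , n], kernels[[i]])
  }
  pre <- maps <- vector("list", K)
  for (k in seq_len(K)) {
    s <- matrix(layer_params$zeta[k], nrow(x), ncol(x))
    for (n in seq_len(N)) for (m in seq_len(M))
      s <- s + layer_params$gamma[k, m, n] * resp[[(n - 1) * M + m]]
    pre[[k]] <- s
    maps[[k]] <- .sigmoid(s)
  }
  if (cache) list(maps = maps, pre = pre, resp = resp, kernels = kernels,
                  x = x)
  else list(maps = maps)
}

#' Element-wise product of probability maps
#'
#' Parameter-free per-pixel product of K maps in \[0,1\]; acts as a soft
#' logical AND, highlighting pixels supported by every map.
#'
#' @param maps List of >= 2 equally sized matrices with values in \[0,1\].
#' @return A single matrix.
#' @export
elementwise_product <- function(maps) {
  if (length(maps) < 2) stop("need at least two maps")
  d <- dim(maps[[1]])
  for (m in maps[-1]) if (!identical(dim(m), d)) stop("map shapes differ")
  Reduce(`*`, maps)
}

#' Forward pass of a DoGNet
#'
#' Applies the configured layers in sequence; each layer's K sigmoid maps
#' feed the next layer as channels.  With `use_product` the final K maps
#' are merged into one probability map.
#'
#' @param x Input image: matrix, 3D array `[row, col, channel]`, or a
#'   [channel_stack()].
#' @param params A `dognet_params` object matching `config`.
#' @param config A [dognet_config()].
#' @param cache Keep per-layer intermediates for backpropagation.
#' @return The probability map (matrix in \[0,1\]); with `cache = TRUE` a
#'   list with the map and layer caches.
#' @export
dognet_forward <- function(x, params, config, cache = FALSE) {
  x <- .as_stack_array(x)
  Tn <- length(config$layers)
  caches <- vector("list", Tn)
  cur <- x
  for (t in seq_len(Tn)) {
    out <- dognet_layer_forward(cur, params[[t]], config$layers[[t]],
                                config$support, cache = cache)
    caches[[t]] <- out
    cur <- .maps_to_array(out$maps)
  }
  maps <- out$maps
  prob <- if (config$use_product) elementwise_product(maps) else maps[[1]]
  if (cache) list(map = prob, layers = caches) else prob
}

.as_stack_array <- function(x) {
  if (inherits(x, "channel_stack")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3) stop("input must be a matrix or [row, col, channel] array")
  x
}

.maps_to_array <- function(maps) {
  array(unlist(maps), c(dim(maps[[1]]), length(maps)))
}

## ---- checkpoints: flat named-value serialization ----

#' Flatten DoGNet parameters to a named vector
#'
#' Names follow `L<t>.c<n>.f<m>.<param>` for filter parameters,
#' `L<t>.gamma.k<k>.m<m>.n<n>` for mixing weights and `L<t>.zeta.k<k>` for
#' biases, so a checkpoint is a flat, explicitly named record.
#'
#' @param params A `dognet_params` object.
#' @return Named numeric vector.
#' @export
flatten_params <- function(params) {
  out <- c()
  for (t in seq_along(params)) {
    lp <- params[[t]]
    for (n in seq_along(lp$beta)) for (m in seq_along(lp$beta[[n]])) {
      p <- lp$beta[[n]][[m]]
      names(p) <- sprintf("L%d.c%d.f%d.%s", t, n, m, names(p))
      out <- c(out, unclass(p))
    }
    K <- dim(lp$gamma)[1]; M <- dim(lp$gamma)[2]; N <- dim(lp$gamma)[3]
    for (nn in seq_len(N)) for (mm in seq_len(M)) for (kk in seq_len(K))
      out[sprintf("L%d.gamma.k%d.m%d.n%d", t, kk, mm, nn)] <-
        lp$gamma[kk, mm, nn]
    for (kk in seq_len(K))
      out[sprintf("L%d.zeta.k%d", t, kk)] <- lp$zeta[kk]
  }
  out
}

#' Rebuild DoGNet parameters from a flat named vector
#'
#' Inverse of [flatten_params()] given the architecture.
#'
#' @param flat Named numeric vector as produced by [flatten_params()].
#' @param config A [dognet_config()].
#' @return A `dognet_params` object.
#' @export
unflatten_params <- function(flat, config) {
  layers <- vector("list", length(config$layers))
  for (t in seq_along(config$layers)) {
    lc <- config$layers[[t]]
    M <- lc$filters_per_channel; N <- lc$n_in; K <- lc$n_out
    pn <- .dog_param_names(lc$kind)
    beta <- lapply(seq_len(N), function(n) lapply(seq_len(M), function(m) {
      v <- flat[sprintf("L%d.c%d.f%d.%s", t, n, m, pn)]
      names(v) <- pn
      structure(v, kind = lc$kind, class = "dog_params")
    }))
    gamma <- array(NA_real_, c(K, M, N))
    for (nn in seq_len(N)) for (mm in seq_len(M)) for (kk in seq_len(K))
      gamma[kk, mm, nn] <- flat[[sprintf("L%d.gamma.k%d.m%d.n%d", t, kk, mm, nn)]]
    zeta <- as.numeric(flat[sprintf("L%d.zeta.k%d", t, seq_len(K))])
    layers[[t]] <- list(beta = beta, gamma = gamma, zeta = zeta)
  }
  structure(layers, class = "dognet_params")
}

#' Save / load a DoGNet checkpoint
#'
#' A checkpoint is a JSON document holding the architecture (layer shapes,
#' filter kind, product head, support size) and the flat named parameter
#' vector; round-trip stable at full double precision.
#'
#' @param params A `dognet_params` object.
#' @param config The matching [dognet_config()].
#' @param path File path.
#' @return `read_checkpoint` returns `list(config, params)`.
#' @export
write_checkpoint <- function(params, config, path) {
  doc <- list(
    format = "dognet-checkpoint-1",
    layers = lapply(config$layers, function(lc)
      list(n_in = lc$n_in, filters_per_channel = lc$filters_per_channel,
           n_out = lc$n_out, kind = lc$kind)),
    use_product = config$use_product,
    support_size = 2L * config$support$half + 1L,
    values = as.list(flatten_params(params)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "dognet-checkpoint-1"))
    stop("not a DoGNet checkpoint: ", path)
  layers <- lapply(doc$layers, function(l)
    dognet_layer_config(l$n_in, l$filters_per_channel, l$n_out, l$kind))
  config <- dognet_config(layers = layers, use_product = doc$use_product,
                          support_size = doc$support_size,
                          n_channels = layers[[1]]$n_in)
  flat <- unlist(doc$values)
  list(config = config, params = unflatten_params(flat, config))
}
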