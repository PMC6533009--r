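## The modelling interface: fit a DoGNet to an annotated image, returning
## a classed object with the usual print / summary / coef / predict /
## plot / residuals / simulate methods.

#' Fit a DoGNet to an annotated multiplexed image
#'
#' Rasterizes the point annotations into a binary disk mask, z-scores each
#' channel, and minimizes the soft-Dice loss between the network's
#' probability map and the mask over randomly cropped patches by Adam.
#'
#' @param x Training image: a [channel_stack()], 3D array
#'   `[row, col, channel]`, or matrix.
#' @param annotations Data frame of synapse centroids (`x`, `y`, optional
#'   `unit` column), or a pre-rasterized binary mask matrix.
#' @param config A [dognet_config()]; defaults to the shallow isotropic
#'   architecture for the input's channel count.
#' @param control A [dognet_control()].
#' @param pixel_size Micrometers per pixel; taken from the stack when
#'   given.
#' @return A `dognet` object with components `config`, `params` (fitted),
#'   `init_params`, `loss` (per-epoch trace), `control`, `pixel_size`,
#'   `channels`, and the training data (`x`, `mask`).
#' @seealso [predict.dognet()], [dognet_train()] for the bare optimizer.
#' @examples
#' \donttest{
#' scene <- generate_scene(synthetic_config(size = 64, n_excitatory = 6,
#'                                          n_spurious = 2, seed = 7))
#' fit <- dognet_fit(scene$stack,
#'                   scene$truth[grep("spurious", scene$truth$type,
#'                                    invert = TRUE), ],
#'                   control = dognet_control(epochs = 200, seed = 7))
#' print(fit)
#' }
#' @export
dognet_fit <- function(x, annotations, config = NULL,
                       control = dognet_control(), pixel_size = NULL) {
  cl <- match.call()
  if (inherits(x, "channel_stack")) {
    if (is.null(pixel_size)) pixel_size <- x$pixel_size
    channels <- x$channels
    x <- x$data
  } else {
    x <- .as_stack_array(x)
    channels <- paste0("ch", seq_len(dim(x)[3]) - 1)
  }
  if (is.null(pixel_size)) pixel_size <- 0.2
  if (is.null(config)) config <- dognet_config(n_channels = dim(x)[3])
  if (config$layers[[1]]$n_in != dim(x)[3])
    stop("input has ", dim(x)[3], " channels but the model expects ",
         config$layers[[1]]$n_in)
  mask <- if (is.matrix(annotations)) annotations else
    rasterize_mask(annotations, dim(x)[1:2], control$mask_radius,
                   pixel_size)
  xn <- if (control$normalize) normalize_channels(x) else x
  init <- dognet_init(config, control$seed)
  res <- dognet_train(xn, mask, config, init, control)
  structure(list(config = config, params = res$params,
                 init_params = init, loss = res$loss, control = control,
                 pixel_size = pixel_size, channels = channels,
                 x = x, mask = mask, call = cl),
            class = "dognet")
}

#' @export
print.dognet <- function(x, ...) {
  Tn <- length(x$config$layers)
  lc <- x$config$layers[[1]]
  cat("DoGNet (", if (Tn == 1) "shallow" else paste0("deep, T = ", Tn),
      ", ", lc$kind, ")\n", sep = "")
  cat("  channels:", lc$n_in, " filters/channel:", lc$filters_per_channel,
      " output maps:", x$config$layers[[Tn]]$n_out,
      if (x$config$use_product) "(element-wise product head)", "\n")
  cat("  trainable parameters:", count_parameters(x$config), "\n")
  cat("  epochs:", length(x$loss),
      " final soft-Dice loss:", signif(utils::tail(x$loss, 1), 4), "\n")
  invisible(x)
}

#' @export
summary.dognet <- function(object, ...) {
  sig <- flatten_params(object$params)
  sig <- sig[grepl("\\.sigma", names(sig))]
  s <- list(model = object,
            n_params = count_parameters(object$config),
            loss_first = object$loss[1],
            loss_final = utils::tail(object$loss, 1),
            sigma_range = range(sig),
            mask_fraction = mean(object$mask))
  class(s) <- "summary.dognet"
  s
}

#' @export
print.summary.dognet <- function(x, ...) {
  print(x$model)
  cat("  fitted sigma range: [", signif(x$sigma_range[1], 4), ", ",
      signif(x$sigma_range[2], 4), "] px\n", sep = "")
  cat("  loss: ", signif(x$loss_first, 4), " (epoch 1) -> ",
      signif(x$loss_final, 4), " (final)\n", sep = "")
  cat("  positive mask fraction: ", signif(x$mask_fraction, 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.dognet <- function(object, ...) flatten_params(object$params)

#' Predict probability maps or detections from a fitted DoGNet
#'
#' @param object A fitted [dognet_fit()] model.
#' @param newdata A [channel_stack()] or array; defaults to the training
#'   image.
#' @param type `"map"` for the probability map, `"detections"` for the
#'   post-processed detection table (with per-channel punctum descriptors).
#' @param tau Confidence threshold for detections (default 0.5).
#' @param R Non-maximum-suppression radius in micrometers (default 1.6).
#' @param descriptors Fit per-channel Gaussian descriptors (default TRUE).
#' @param ... Unused.
#' @return A matrix in \[0,1\] or a detection data frame.
#' @export
predict.dognet <- function(object, newdata = NULL,
                           type = c("map", "detections"), tau = 0.5,
                           R = 1.6, descriptors = TRUE, ...) {
  type <- match.arg(type)
  pixel_size <- object$pixel_size
  if (is.null(newdata)) newdata <- object$x
  if (inherits(newdata, "channel_stack")) {
    pixel_size <- newdata$pixel_size
    raw <- newdata$data
  } else raw <- .as_stack_array(newdata)
  xn <- if (object$control$normalize) normalize_channels(raw) else raw
  map <- dognet_forward(xn, object$params, object$config)
  if (type == "map") return(map)
  detect_synapses(map, tau = tau, R = R, pixel_size = pixel_size,
                  channels = if (descriptors)
                    channel_stack(raw, object$channels, pixel_size))
}

#' @export
fitted.dognet <- function(object, ...) predict(object, type = "map")

#' @export
residuals.dognet <- function(object, ...) object$mask - fitted(object)

#' Plot a fitted DoGNet
#'
#' `which = "loss"` draws the training loss trace; `which = "kernels"`
#' draws the fitted DoG kernels of the first layer, one row per channel.
#'
#' @param x A fitted `dognet` object.
#' @param which `"loss"` or `"kernels"`.
#' @param ... Passed to the underlying plotting functions.
#' @export
plot.dognet <- function(x, which = c("loss", "kernels"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    graphics::plot(seq_along(x$loss), x$loss, type = "l",
                   xlab = "epoch", ylab = "soft-Dice loss",
                   main = "DoGNet training", ...)
  } else {
    lc <- x$config$layers[[1]]
    old <- graphics::par(mfrow = c(lc$n_in, lc$filters_per_channel),
                         mar = c(0.5, 0.5, 1.5, 0.5))
    on.exit(graphics::par(old))
    for (n in seq_len(lc$n_in)) for (m in seq_len(lc$filters_per_channel)) {
      k <- dog_kernel(x$params[[1]]$beta[[n]][[m]], x$config$support)
      graphics::image(k, axes = FALSE, col = grDevices::hcl.colors(64),
                      main = paste0(x$channels[n], " / f", m), cex.main = 0.8)
    }
  }
  invisible(x)
}

#' Simulate synthetic scenes matching a fitted model
#'
#' Generates synthetic multiplexed scenes with the same channel count as
#' the fitted network (three-channel excitatory or five-channel
#' excitatory + inhibitory layout), useful for held-out evaluation.
#'
#' @param object A fitted `dognet` object.
#' @param nsim Number of scenes.
#' @param seed Base seed; scene i uses `seed + i - 1`.
#' @param config A [synthetic_config()] overriding the default scene.
#' @param ... Unused.
#' @return List of `synthetic_scene` objects (length `nsim`).
#' @export
simulate.dognet <- function(object, nsim = 1, seed = 1, config = NULL,
                            ...) {
  nch <- object$config$layers[[1]]$n_in
  if (is.null(config)) {
    if (!nch %in% c(3, 5))
      stop("no default scene layout for ", nch, " channels; pass config")
    config <- synthetic_config(pixel_size = object$pixel_size,
                               n_inhibitory = if (nch == 5) 8 else 0)
  }
  lapply(seq_len(nsim), function(i) generate_scene(config, seed + i - 1))
}
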