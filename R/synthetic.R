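## Synthetic multiplexed puncta scenes with ground truth: true synapses
## (colocalized puncta on both sides), spurious single-sided synapses, and
## additive white noise at a controlled signal-to-noise ratio.

#' Marker channel layout
#'
#' Ordered channel labels with their synaptic roles.  The default
#' excitatory three-channel layout is synapsin (presynaptic, shared),
#' vGlut (presynaptic, excitatory) and PSD-95 (postsynaptic, excitatory);
#' `inhibitory = TRUE` appends vGat (presynaptic, inhibitory) and gephyrin
#' (postsynaptic, inhibitory).
#'
#' @param inhibitory Include the inhibitory marker channels.
#' @return A `marker_layout` data frame with columns `channel`, `side`
#'   (`pre`/`post`) and `subtype` (`shared`/`excitatory`/`inhibitory`).
#' @export
marker_layout <- function(inhibitory = FALSE) {
  l <- data.frame(
    channel = c("synapsin", "vGlut", "PSD-95"),
    side = c("pre", "pre", "post"),
    subtype = c("shared", "excitatory", "excitatory"))
  if (inhibitory)
    l <- rbind(l, data.frame(channel = c("vGat", "gephyrin"),
                             side = c("pre", "post"),
                             subtype = c("inhibitory", "inhibitory")))
  structure(l, class = c("marker_layout", "data.frame"))
}

#' Synthetic scene configuration
#'
#' @param size Image side in pixels (square scenes).
#' @param n_excitatory,n_inhibitory Counts of true excitatory/inhibitory
#'   synapses (inhibitory requires the five-channel layout).
#' @param n_spurious Count of spurious single-sided synapses, split evenly
#'   between presynaptic-only and postsynaptic-only.
#' @param punctum_sigma Gaussian punctum bandwidth in pixels (default 1,
#'   a diffraction-limited spot at 0.1-0.2 um/px).
#' @param max_displacement Maximum inter-marker punctum displacement in
#'   pixels; each channel's punctum is offset independently and uniformly
#'   in a disk of this radius.
#' @param snr Target signal-to-noise ratio: mean punctum peak amplitude
#'   over the noise standard deviation.
#' @param intensity_sigma Log-normal sigma of punctum intensities
#'   (default 0.1, zero log-mean).
#' @param pixel_size Micrometers per pixel (default 0.2).
#' @param min_separation Minimum distance between synapse centers in
#'   pixels; defaults to the suppression radius `1.6 / pixel_size` so
#'   ground truth stays resolvable under NMS while allowing the study's
#'   synapse density (~96 per 128 x 128).
#' @param layout A [marker_layout()]; chosen from the counts when `NULL`.
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(size = 128, n_excitatory = 64,
                             n_inhibitory = 0, n_spurious = 32,
                             punctum_sigma = 1, max_displacement = 2,
                             snr = 3, intensity_sigma = 0.1,
                             pixel_size = 0.2, min_separation = NULL,
                             layout = NULL, seed = 1) {
  stopifnot(size >= 16, n_excitatory >= 0, n_inhibitory >= 0,
            n_spurious >= 0, snr > 0, max_displacement >= 0,
            punctum_sigma > 0, intensity_sigma >= 0)
  if (is.null(layout)) layout <- marker_layout(inhibitory = n_inhibitory > 0)
  if (n_inhibitory > 0 && !"inhibitory" %in% layout$subtype)
    stop("inhibitory synapses require the five-channel layout")
  if (is.null(min_separation)) min_separation <- 1.6 / pixel_size
  structure(list(size = as.integer(size), n_excitatory = n_excitatory,
                 n_inhibitory = n_inhibitory, n_spurious = n_spurious,
                 punctum_sigma = punctum_sigma,
                 max_displacement = max_displacement, snr = snr,
                 intensity_sigma = intensity_sigma, pixel_size = pixel_size,
                 min_separation = min_separation, layout = layout,
                 seed = seed),
            class = "synthetic_config")
}

## uniformly place n points with a minimum pairwise separation (dart
## throwing); errors, naming the achieved count, if infeasible
.place_centers <- function(n, size, sep, margin, max_tries = 20000L) {
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < max_tries) {
    tries <- tries + 1L
    x <- stats::runif(1, margin, size - 1 - margin)
    y <- stats::runif(1, margin, size - 1 - margin)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= sep^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < n)
    stop("could not place ", n, " synapses at separation ", round(sep, 2),
         " px in a ", size, " x ", size, " image; achieved ", length(xs),
         call. = FALSE)
  data.frame(x = xs, y = ys)
}

#' Generate a synthetic multiplexed scene
#'
#' Synapse centers are placed uniformly at random subject to the minimum
#' separation.  A true synapse renders one Gaussian punctum in every
#' channel of its side/subtype (synapsin plus vGlut and PSD-95 for
#' excitatory; synapsin plus vGat and gephyrin for inhibitory), each
#' displaced independently and uniformly in a disk of radius
#' `max_displacement`; spurious synapses render puncta on exactly one
#' side.  Punctum amplitudes are `exp(N(0, intensity_sigma))` draws,
#' globally rescaled so that the mean rendered peak amplitude over the
#' noise standard deviation (1.0) equals the target SNR; finally white
#' Gaussian noise is added to every channel.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `synthetic_scene` list: `stack` (a [channel_stack()]),
#'   `truth` (data frame `x`, `y`, `type` in 0-based pixels; types
#'   `excitatory`, `inhibitory`, `spurious-pre`, `spurious-post`),
#'   `clean` (noise-free array), `noise_sd`, `puncta` (per-punctum table),
#'   and the `config`.
#' @export
generate_scene <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  restore <- .with_preserved_rng(seed)
  on.exit(restore())
  lay <- config$layout
  nch <- nrow(lay)
  size <- config$size
  ## border margin independent of the displacement level so that sweeps
  ## over displacement keep identical synapse placements
  margin <- 3 * config$punctum_sigma + 5
  n_total <- config$n_excitatory + config$n_inhibitory + config$n_spurious
  centers <- .place_centers(n_total, size, config$min_separation, margin)
  n_sp_pre <- ceiling(config$n_spurious / 2)
  types <- c(rep("excitatory", config$n_excitatory),
             rep("inhibitory", config$n_inhibitory),
             rep("spurious-pre", n_sp_pre),
             rep("spurious-post", config$n_spurious - n_sp_pre))
  truth <- cbind(centers, data.frame(type = types))

  ## channels receiving a punctum for a synapse of a given type
  chans_for <- function(type) {
    pre <- lay$side == "pre"; post <- lay$side == "post"
    exc <- lay$subtype %in% c("shared", "excitatory")
    inh <- lay$subtype %in% c("shared", "inhibitory")
    which(switch(type,
      "excitatory" = exc & (pre | post),
      "inhibitory" = inh & (pre | post),
      ## spurious sides: excitatory subtype puncta, one side only
      "spurious-pre" = exc & pre,
      "spurious-post" = exc & post))
  }

  ## draw all punctum placements first (per synapse, per channel), then
  ## render channel by channel so each image plane is built in place
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (ch in chans_for(truth$type[i])) {
      theta <- stats::runif(1, 0, 2 * pi)
      rad <- config$max_displacement * sqrt(stats::runif(1))
      rows[[length(rows) + 1]] <- data.frame(
        synapse = i, channel = lay$channel[ch],
        x = truth$x[i] + rad * cos(theta),
        y = truth$y[i] + rad * sin(theta),
        amp = exp(stats::rnorm(1, 0, config$intensity_sigma)))
    }
  }
  puncta <- if (length(rows)) do.call(rbind, rows) else
    data.frame(synapse = integer(), channel = character(),
               x = numeric(), y = numeric(), amp = numeric())
  clean <- array(0, c(size, size, nch))
  sig <- config$punctum_sigma
  r <- ceiling(5 * sig)
  for (ch in seq_len(nch)) {
    img <- matrix(0, size, size)
    pk <- puncta[puncta$channel == lay$channel[ch], ]
    for (i in seq_len(nrow(pk))) {
      cx <- pk$x[i]; cy <- pk$y[i]
      cols <- max(1, floor(cx) - r + 1):min(size, ceiling(cx) + r + 1)
      rws <- max(1, floor(cy) - r + 1):min(size, ceiling(cy) + r + 1)
      gx <- exp(-((cols - 1 - cx)^2) / (2 * sig^2))
      gy <- exp(-((rws - 1 - cy)^2) / (2 * sig^2))
      img[rws, cols] <- img[rws, cols] + pk$amp[i] * outer(gy, gx)
    }
    clean[, , ch] <- img
  }
  ## calibrate the global amplitude scale so that the mean *rendered* peak
  ## (max of the clean image in the 3x3 around each punctum center) over
  ## the unit noise sd hits the target SNR
  noise_sd <- 1.0
  mean_peak <- .mean_rendered_peak(clean, puncta, lay)
  scale <- config$snr * noise_sd / mean_peak
  clean <- clean * scale
  puncta$amp <- puncta$amp * scale
  noisy <- clean + array(stats::rnorm(length(clean), 0, noise_sd),
                         dim(clean))
  stack <- channel_stack(noisy, channels = lay$channel,
                         pixel_size = config$pixel_size)
  structure(list(stack = stack, truth = truth, clean = clean,
                 noise_sd = noise_sd, puncta = puncta, config = config),
            class = "synthetic_scene")
}

.mean_rendered_peak <- function(clean, puncta, lay) {
  if (is.null(puncta) || nrow(puncta) == 0) return(NA_real_)
  n <- dim(clean)[1]
  peaks <- vapply(seq_len(nrow(puncta)), function(i) {
    ch <- match(puncta$channel[i], lay$channel)
    r <- round(puncta$y[i]) + 1; cc <- round(puncta$x[i]) + 1
    rows <- max(1, r - 1):min(n, r + 1)
    cols <- max(1, cc - 1):min(dim(clean)[2], cc + 1)
    max(clean[rows, cols, ch])
  }, 0)
  mean(peaks)
}

#' Measured per-channel signal-to-noise ratio of a scene
#'
#' Mean rendered peak amplitude (from the scene's internal noise-free
#' reference) divided by the realized noise standard deviation, per
#' channel.  Channels without puncta yield `NA`; a zero-noise scene
#' reports `Inf`.
#'
#' @param scene A [generate_scene()] result.
#' @return Named numeric vector, one value per channel.
#' @export
measure_snr <- function(scene) {
  lay <- scene$config$layout
  noise <- scene$stack$data - scene$clean
  out <- stats::setNames(rep(NA_real_, nrow(lay)), lay$channel)
  for (ch in seq_len(nrow(lay))) {
    pk <- scene$puncta[scene$puncta$channel == lay$channel[ch], ]
    if (nrow(pk) == 0) next
    sub <- scene$clean[, , ch, drop = FALSE]
    dim(sub) <- dim(sub)[1:2]
    mp <- .mean_rendered_peak(array(sub, c(dim(sub), 1)),
                              transform(pk, channel = lay$channel[ch]),
                              lay[ch, , drop = FALSE])
    ns <- stats::sd(noise[, , ch])
    out[ch] <- if (ns == 0) Inf else mp / ns
  }
  out
}

#' Paired train/test scenes along one difficulty axis
#'
#' Builds the sensitivity-study suites: pairs of (train, test) scenes that
#' vary only the named axis — `snr`, `displacement` (max punctum offset in
#' pixels) or `train_size` (training image side in pixels) — with all
#' other parameters and the test-scene seed held fixed, so test difficulty
#' is constant across levels (except when the swept axis itself alters the
#' scene statistics).
#'
#' @param axis One of `"snr"`, `"displacement"`, `"train_size"`.
#' @param levels Numeric vector of axis values.
#' @param base A [synthetic_config()] for the training scenes; the test
#'   scene uses the same parameters at size 128 with proportional counts.
#' @param test_seed Seed of every test scene (default `base$seed + 10000`).
#' @return List (one per level) of `list(level, train, test)`.
#' @export
make_benchmark_suite <- function(axis = c("snr", "displacement",
                                          "train_size"),
                                 levels, base = synthetic_config(),
                                 test_seed = NULL) {
  axis <- match.arg(axis)
  if (is.null(test_seed)) test_seed <- base$seed + 10000L
  lapply(levels, function(lv) {
    tr_cfg <- te_cfg <- base
    if (axis == "snr") tr_cfg$snr <- te_cfg$snr <- lv
    else if (axis == "displacement")
      tr_cfg$max_displacement <- te_cfg$max_displacement <- lv
    else {
      stopifnot(lv >= 16)
      tr_cfg$size <- as.integer(lv)
      ## keep synapse density constant when shrinking the training scene
      f <- (lv / base$size)^2
      tr_cfg$n_excitatory <- max(1L, round(base$n_excitatory * f))
      tr_cfg$n_inhibitory <- round(base$n_inhibitory * f)
      tr_cfg$n_spurious <- round(base$n_spurious * f)
    }
    list(level = lv,
         train = generate_scene(tr_cfg),
         test = generate_scene(te_cfg, seed = test_seed))
  })
}
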