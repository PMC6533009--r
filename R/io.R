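## File I/O: multi-channel float TIFF stacks, annotation and detection
## tables, run configuration documents, and channel harmonization.

#' Multi-channel image stack
#'
#' Named 2D channels of equal shape with pixel-size metadata.  The
#' coordinate convention throughout the package is 0-based pixel indices,
#' `(x, y) = (column, row)`, origin at the top-left; micrometer
#' coordinates are `pixel * pixel_size`.
#'
#' @param data 3D array `[row, col, channel]`, a matrix (one channel), or
#'   a list of equal-shaped matrices.
#' @param channels Character vector of unique channel names; defaults to
#'   `ch0, ch1, ...`.
#' @param pixel_size Pixel size in micrometers per pixel.
#' @return A `channel_stack` object.
#' @export
channel_stack <- function(data, channels = NULL, pixel_size = 0.2) {
  if (is.list(data) && !is.array(data)) {
    d <- dim(data[[1]])
    for (m in data) if (!identical(dim(m), d))
      stop("all channels must share the same shape")
    data <- array(unlist(data), c(d, length(data)))
  }
  data <- .as_stack_array(data)
  nch <- dim(data)[3]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nch) - 1)
  channels <- as.character(channels)
  if (length(channels) != nch) stop("need one name per channel")
  if (anyDuplicated(channels)) stop("channel names must be unique")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be a positive number (um/pixel)")
  structure(list(data = data, channels = channels,
                 pixel_size = pixel_size),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat("channel_stack:", d[1], "x", d[2], "px,", d[3], "channel(s) [",
      paste(x$channels, collapse = ", "), "],",
      x$pixel_size, "um/px\n")
  invisible(x)
}

## ---- minimal multi-page 32-bit-float TIFF writer ----
## The tiff package reads float TIFFs but writes only unsigned-integer
## samples scaled to [0, 1], so probability maps and raw-intensity scenes
## are written here directly: little-endian, uncompressed, one strip per
## page, SampleFormat = IEEE float, channel names and pixel size in a JSON
## ImageDescription tag on the first page.
.write_float_tiff <- function(planes, path, description = "") {
  nr <- nrow(planes[[1]]); nc <- ncol(planes[[1]])
  npage <- length(planes)
  desc_raw <- c(charToRaw(description), as.raw(0))
  if (length(desc_raw) %% 2 == 1) desc_raw <- c(desc_raw, as.raw(0))
  data_bytes <- 4L * nr * nc
  ifd_bytes <- function(n_entries) 2L + 12L * n_entries + 4L
  n_entries <- c(11L, rep(10L, max(0, npage - 1)))
  ## layout: header | description | (data, ifd) per page
  desc_off <- 8L
  data_off <- integer(npage); ifd_off <- integer(npage)
  cur <- desc_off + length(desc_raw)
  for (p in seq_len(npage)) {
    data_off[p] <- cur
    ifd_off[p] <- cur + data_bytes
    cur <- ifd_off[p] + ifd_bytes(n_entries[p])
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wb(charToRaw("II"), 1L)
  wb(42L, 2)
  wb(ifd_off[1], 4)
  writeBin(desc_raw, con)
  entry <- function(tag, type, count, value) {
    wb(as.integer(tag), 2); wb(as.integer(type), 2)
    wb(as.integer(count), 4)
    if (type == 3) { wb(as.integer(value), 2); wb(0L, 2) }
    else wb(as.integer(value), 4)
  }
  for (p in seq_len(npage)) {
    writeBin(as.vector(t(planes[[p]])), con, size = 4, endian = "little")
    wb(n_entries[p], 2)
    entry(256, 4, 1, nc)                       # ImageWidth
    entry(257, 4, 1, nr)                       # ImageLength
    entry(258, 3, 1, 32)                       # BitsPerSample
    entry(259, 3, 1, 1)                        # Compression: none
    entry(262, 3, 1, 1)                        # Photometric: BlackIsZero
    if (p == 1) entry(270, 2, length(desc_raw), desc_off)
    entry(273, 4, 1, data_off[p])              # StripOffsets
    entry(277, 3, 1, 1)                        # SamplesPerPixel
    entry(278, 4, 1, nr)                       # RowsPerStrip
    entry(279, 4, 1, data_bytes)               # StripByteCounts
    entry(339, 3, 1, 3)                        # SampleFormat: IEEE float
    wb(if (p < npage) ifd_off[p + 1] else 0L, 4)
  }
  invisible(path)
}

#' Write a channel stack as a multi-page float TIFF
#'
#' One 32-bit-float page per channel; channel names and the pixel size are
#' stored as JSON in the ImageDescription tag, so a stack round-trips
#' through [read_stack()] with metadata intact and values exact to
#' float32 precision.
#'
#' @param stack A [channel_stack()] (or matrix/array, with `channels` and
#'   `pixel_size` taken from the arguments).
#' @param path Output file path.
#' @inheritParams channel_stack
#' @return The path, invisibly.
#' @export
write_stack <- function(stack, path, channels = NULL, pixel_size = 0.2) {
  if (!inherits(stack, "channel_stack"))
    stack <- channel_stack(stack, channels, pixel_size)
  planes <- lapply(seq_along(stack$channels),
                   function(ch) stack$data[, , ch])
  meta <- jsonlite::toJSON(list(channels = stack$channels,
                                pixel_size_um = stack$pixel_size),
                           auto_unbox = TRUE, digits = NA)
  .write_float_tiff(planes, path, as.character(meta))
}

#' Read a multi-channel TIFF into a channel stack
#'
#' Accepts any multi-page (or single-page) TIFF readable by the tiff
#' package.  Channel names and pixel size are taken from the JSON
#' ImageDescription written by [write_stack()] when present, otherwise
#' names fall back to `ch0, ch1, ...` and the pixel size to the
#' `pixel_size` argument; an error is raised if neither source provides
#' one.
#'
#' @param path TIFF file path.
#' @param pixel_size Pixel size override in micrometers per pixel.
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL) {
  planes <- suppressWarnings(tiff::readTIFF(path, all = TRUE, info = TRUE))
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) < 1) stop("no image planes in ", path)
  d <- dim(planes[[1]])[1:2]
  for (p in planes) if (!identical(dim(p)[1:2], d))
    stop("image planes in ", path, " have mismatched shapes")
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # collapse RGB pages to gray
  })
  meta <- NULL
  desc <- attr(planes[[1]], "description")
  if (!is.null(desc))
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
  channels <- if (!is.null(meta$channels)) meta$channels else NULL
  ps <- if (!is.null(pixel_size)) pixel_size else meta$pixel_size_um
  if (is.null(ps))
    stop("no pixel size in TIFF metadata; pass pixel_size explicitly")
  channel_stack(planes, channels = channels, pixel_size = ps)
}

## ---- annotation and detection tables ----

.header_comment <- paste(
  "# coordinates: 0-based pixels, (x, y) = (column, row), origin",
  "top-left; um = pixel * pixel_size")

#' Read / write annotation tables
#'
#' Delimited text (comma, header row) with columns `x`, `y` and optional
#' `unit` (`px` or `um`) and `expert` columns; coordinates are 0-based,
#' pixel units unless the unit column says `um`.  Lines starting with `#`
#' are ignored.
#'
#' @param path File path.
#' @param annotations Data frame with at least `x` and `y`.
#' @return `read_annotations` returns the data frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("x", "y") %in% names(df)))
    stop("annotation table needs columns x and y")
  df
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  writeLines(.header_comment, path)
  suppressWarnings(utils::write.table(
    annotations, path, sep = ",", row.names = FALSE, append = TRUE,
    quote = FALSE))
  invisible(path)
}

#' Write a detection table
#'
#' Comma-delimited with a comment line stating the coordinate convention;
#' columns `x`, `y` (pixels), `x_um`, `y_um`, `confidence`, plus any
#' per-channel descriptor columns.
#'
#' @param detections Detection data frame.
#' @param path File path.
#' @export
write_detections <- function(detections, path) {
  writeLines(.header_comment, path)
  suppressWarnings(utils::write.table(
    detections, path, sep = ",", row.names = FALSE, append = TRUE,
    quote = FALSE))
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) utils::read.csv(path, comment.char = "#")

#' Write a training loss trace
#'
#' @param loss Numeric vector of per-epoch losses.
#' @param path File path.
#' @export
write_loss_trace <- function(loss, path) {
  utils::write.csv(data.frame(epoch = seq_along(loss), loss = loss), path,
                   row.names = FALSE)
  invisible(path)
}

## ---- channel harmonization for cross-dataset transfer ----

#' Per-channel intensity statistics
#'
#' @param stack A [channel_stack()].
#' @return Data frame with columns `channel`, `mean`, `sd`.
#' @export
channel_stats <- function(stack) {
  data.frame(channel = stack$channels,
             mean = vapply(seq_along(stack$channels),
                           function(ch) mean(stack$data[, , ch]), 0),
             sd = vapply(seq_along(stack$channels),
                         function(ch) stats::sd(stack$data[, , ch]), 0))
}

#' Harmonize a stack to reference channel statistics
#'
#' Applies a linear intensity transform per channel so its mean and
#' standard deviation match the reference, and resamples the image by the
#' magnification ratio, so a network trained on the reference dataset can
#' be applied directly.  Being affine per channel, the transform preserves
#' the correlation structure between channels.
#'
#' @param stack A [channel_stack()].
#' @param reference_stats Data frame as from [channel_stats()], matched by
#'   channel name.
#' @param scale Resize factor (target pixels per source pixel; default 1).
#' @return A harmonized [channel_stack()]; `pixel_size` is divided by
#'   `scale`.
#' @export
harmonize_channels <- function(stack, reference_stats, scale = 1) {
  stopifnot(inherits(stack, "channel_stack"), scale > 0)
  out <- stack$data
  for (ch in seq_along(stack$channels)) {
    ref <- reference_stats[reference_stats$channel == stack$channels[ch], ]
    if (nrow(ref) != 1)
      stop("no reference statistics for channel ", stack$channels[ch])
    v <- out[, , ch]
    s <- stats::sd(v)
    if (s == 0) stop("channel ", stack$channels[ch], " has zero variance")
    if (ref$sd <= 0) stop("reference sd for channel ", stack$channels[ch],
                          " must be positive")
    out[, , ch] <- (v - mean(v)) / s * ref$sd + ref$mean
  }
  if (scale != 1) {
    d <- dim(out)
    nw <- max(2, round(d[2] * scale)); nh <- max(2, round(d[1] * scale))
    res <- array(0, c(nh, nw, d[3]))
    for (ch in seq_len(d[3]))
      res[, , ch] <- EBImage::resize(out[, , ch], w = nh, h = nw)
    out <- res
  }
  channel_stack(out, stack$channels, stack$pixel_size / scale)
}

## ---- run configuration documents ----

#' Default run configuration
#'
#' One declarative document holding the model, training and
#' post-processing constants: threshold `tau` 0.5, suppression radius `R`
#' 1.6 um, matching radius `rho` 0.6 um, mask radius 0.8 um, kernel
#' support 15 px, 5 filters per channel, deep depth 3.
#'
#' @param ... Overrides of the defaults, as `key = value`.
#' @return Nested list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    model = list(kind = "isotropic-2", filters_per_channel = 5L,
                 n_out = 2L, depth = 1L, use_product = TRUE,
                 support_size = 15L),
    training = list(epochs = 5000L, patches_per_epoch = 10L,
                    patch_size = 64L, mask_radius = 0.8, lr = 0.01),
    postprocess = list(tau = 0.5, R = 1.6, rho = 0.6),
    pixel_size = 0.2,
    seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Read / write a run configuration
#'
#' YAML `key: value` documents; parse -> serialize -> parse is idempotent.
#'
#' @param config Nested list as from [default_run_config()].
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  utils::modifyList(default_run_config(), yaml::read_yaml(path))
}
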