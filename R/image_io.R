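#' Calibrated single-channel image
#'
#' A 2-D intensity raster with optional spatial calibration. This is the
#' package's basic image container: a numeric matrix of non-negative, finite
#' intensities plus an optional pixel size in micrometres per pixel and a
#' channel label.
#'
#' @param pixels Numeric matrix, `pixels[y, x]`, all values finite and >= 0.
#' @param pixel_size Micrometres per pixel (single value > 0), or `NULL` when
#'   the image is uncalibrated; uncalibrated results are reported in pixels
#'   only.
#' @param channel Free-text channel label (e.g. `"GFP"`).
#' @return An object of class `calibrated_image` with fields `pixels`,
#'   `pixel_size`, `channel`.
#' @export
calibrated_image <- function(pixels, pixel_size = NULL, channel = "GFP") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1x1")
  if (!all(is.finite(pixels)))
    stop("all intensities must be finite")
  if (any(pixels < 0))
    stop("all intensities must be >= 0")
  storage.mode(pixels) <- "double"
  if (!is.null(pixel_size)) {
    if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
        !is.finite(pixel_size) || pixel_size <= 0)
      stop("`pixel_size` must be a single value > 0 (um/px)")
    pixel_size <- as.numeric(pixel_size)
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         channel = as.character(channel)[1L]),
    class = "calibrated_image"
  )
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' @export
print.calibrated_image <- function(x, ...) {
  cal <- if (is.null(x$pixel_size)) "uncalibrated"
         else sprintf("%.4g um/px", x$pixel_size)
  cat(sprintf("calibrated_image '%s': %d x %d px, %s, intensity [%g, %g]\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), cal,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Ordered multi-channel image stack
#'
#' Bundles one or more [calibrated_image()] channels sharing dimensions and
#' calibration, addressable by channel name.
#'
#' @param ... `calibrated_image` objects, or a single list of them.
#' @return An object of class `channel_stack` (a named list of channels).
#' @export
channel_stack <- function(...) {
  chans <- list(...)
  if (length(chans) == 1L && !inherits(chans[[1L]], "calibrated_image"))
    chans <- chans[[1L]]
  if (length(chans) == 0L) stop("a channel_stack needs at least one channel")
  ok <- vapply(chans, inherits, logical(1L), "calibrated_image")
  if (!all(ok)) stop("all channels must be calibrated_image objects")
  nms <- vapply(chans, function(ch) ch$channel, character(1L))
  if (anyDuplicated(nms))
    stop("channel names must be unique: ", paste(nms, collapse = ", "))
  d1 <- dim(chans[[1L]]$pixels)
  p1 <- chans[[1L]]$pixel_size
  for (ch in chans[-1L]) {
    if (!identical(dim(ch$pixels), d1))
      stop("all channels must share identical dimensions")
    if (!identical(ch$pixel_size, p1))
      stop("all channels must share identical calibration")
  }
  structure(setNames(chans, nms), class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("channel_stack with %d channel(s): %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Read a multi-channel TIFF micrograph
#'
#' Reads a TIFF / OME-TIFF with 1-4 single-sample 2-D planes into a
#' [channel_stack()]. Pixel-size calibration is resolved in precedence order:
#' the `pixel_size` argument, then a JSON sidecar `<path>.meta.json` (written
#' by [write_stack()]), then an embedded TIFF resolution tag with a physical
#' unit, else none. Channel names come from the sidecar when present,
#' otherwise `"ch1"`, `"ch2"`, ...
#'
#' @param path Path to the TIFF file.
#' @param pixel_size Optional micrometres-per-pixel override.
#' @param channels Optional character vector of channel names to assign
#'   (overrides sidecar names; length must match the page count).
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, channels = NULL) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) stop("cannot read image file: ", path,
                             " (", conditionMessage(e), ")")
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) > 4L)
    stop("unsupported format: ", length(pages),
         " channels (at most 4 supported): ", path)
  for (pg in pages) {
    if (length(dim(pg)) != 2L)
      stop("unsupported format: non-2-D plane (multi-sample pixels?): ", path)
  }

  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp))
    meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                     error = function(e) NULL)

  ps <- pixel_size
  if (is.null(ps) && !is.null(meta$pixel_size) && is.numeric(meta$pixel_size))
    ps <- as.numeric(meta$pixel_size)
  if (is.null(ps)) {
    xres <- attr(pages[[1L]], "x.resolution")
    unit <- attr(pages[[1L]], "resolution.unit")
    if (!is.null(xres) && is.numeric(xres) && xres > 0 &&
        !is.null(unit) && unit %in% c("cm", "inch")) {
      per_um <- if (unit == "cm") xres / 1e4 else xres / 25400
      ps <- 1 / per_um
    }
  }

  nms <- channels
  if (is.null(nms) && !is.null(meta$channels)) nms <- as.character(meta$channels)
  if (is.null(nms)) nms <- paste0("ch", seq_along(pages))
  if (length(nms) != length(pages))
    stop("channel name count (", length(nms), ") does not match page count (",
         length(pages), ")")

  chans <- mapply(function(pg, nm) {
    m <- matrix(as.numeric(pg), nrow = nrow(pg), ncol = ncol(pg))
    calibrated_image(m, pixel_size = ps, channel = nm)
  }, pages, nms, SIMPLIFY = FALSE)
  channel_stack(chans)
}

#' Write a channel stack to a multi-page TIFF with a metadata sidecar
#'
#' Intensities are stored as unsigned integers (8 or 16 bit); calibration and
#' channel names go to `<path>.meta.json` so that [read_stack()] round-trips
#' them (plain TIFF resolution tags cannot carry micrometre units reliably).
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @param bits Bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "channel_stack"), bits %in% c(8L, 16L))
  scale <- 2^bits - 1
  planes <- lapply(stack, function(ch) {
    px <- round(ch$pixels)
    if (any(px > scale))
      stop("intensities exceed ", bits, "-bit range; rescale first")
    px / scale
  })
  ok <- tryCatch({
    tiff::writeTIFF(planes, path, bits.per.sample = bits)
    TRUE
  }, error = function(e) stop("cannot write image file: ", path,
                              " (", conditionMessage(e), ")"))
  meta <- list(channels = names(stack), bits = bits)
  if (!is.null(stack[[1L]]$pixel_size)) meta$pixel_size <- stack[[1L]]$pixel_size
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select one channel from a stack by name or position
#'
#' @param stack A [channel_stack()].
#' @param name Channel name; must be present in the stack.
#' @param index 1-based positional fallback used when `name` is `NULL`
#'   (TIFF dialects do not always label channels).
#' @return The selected [calibrated_image()], unmodified.
#' @export
select_channel <- function(stack, name = NULL, index = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  if (is.null(name) && is.null(index))
    stop("supply a channel `name` or `index`")
  if (!is.null(name)) {
    if (!name %in% names(stack))
      stop("unknown channel '", name, "'; available: ",
           paste(names(stack), collapse = ", "))
    return(stack[[name]])
  }
  if (index < 1L || index > length(stack))
    stop("channel index ", index, " out of range 1..", length(stack))
  stack[[index]]
}

#' Rescale an image linearly to 8-bit
#'
#' Maps `[min, max]` linearly onto integers `0..255` with round-half-up;
#' constant images map to all zeros. Calibration and channel label are
#' preserved. Idempotent on images already spanning the full 0..255 range and
#' monotone (pixel ordering preserved).
#'
#' @param image A [calibrated_image()].
#' @return A [calibrated_image()] with integer intensities in 0..255.
#' @export
to_8bit <- function(image) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  rng <- range(px)
  out <- if (rng[2L] > rng[1L]) {
    floor((px - rng[1L]) / (rng[2L] - rng[1L]) * 255 + 0.5)
  } else {
    array(0, dim(px))
  }
  calibrated_image(out, pixel_size = image$pixel_size, channel = image$channel)
}

#' Write per-particle results and summary metrics
#'
#' Writes the particle table as CSV (one row per particle, ordered by label)
#' and the summary metrics as a JSON sidecar next to it.
#'
#' @param table A particle table from [measure_particles()] (may be empty).
#' @param metrics An `invasion_metrics` object from [summarize_invasion()].
#' @param path Output CSV path; the JSON sidecar is `<path minus .csv>.json`.
#' @return Invisibly, a list with the two paths written.
#' @export
write_results <- function(table, metrics, path) {
  stopifnot(is.data.frame(table))
  tab <- table[order(table$label), , drop = FALSE]
  ok <- tryCatch({
    write.csv(tab, path, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results: ", path,
                              " (", conditionMessage(e), ")"))
  jpath <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(unclass(metrics), jpath, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(list(csv = path, json = jpath))
}
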