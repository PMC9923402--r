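#' Build and validate a batch-run configuration
#'
#' Collects every tunable of the pipeline into one validated object; invalid
#' values abort with a field-specific message before any image is touched.
#'
#' @param input Character vector of TIFF paths and/or globs (expanded with
#'   [Sys.glob()]).
#' @param out_dir Output directory; created if needed.
#' @param channel Tumour-reporter channel name (default `"GFP"`); set to
#'   `NULL` to use `channel_index`.
#' @param channel_index Positional channel fallback (1-based).
#' @param pixel_size Optional micrometres-per-pixel override.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold_value Threshold for `"fixed"`.
#' @param min_hole,min_object Mask-cleaning parameters, px^2.
#' @param ellipse_mode `"auto"` (moments fit) or `"manual"` (per-image
#'   sidecar `<image>.ellipse.json` with fields `cx, cy, a, b, theta_deg`).
#' @param min_area_px2 Strict particle-size filter, px^2.
#' @param h_min_px Watershed peak-depth parameter, px.
#' @param distance_mode `"centroid"` or `"nearest_pixel"`.
#' @param tissue_channel Tissue channel name for slice-surface estimation,
#'   or `NULL` to skip the percent-within-slice measure.
#' @param tissue_threshold Fixed threshold for the tissue channel.
#' @param brain_map Named character vector mapping image ids to brain ids;
#'   unmapped images count as their own brain.
#' @param qc Write a PNG overlay (ellipse + particle outlines) per image.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, out_dir,
                       channel = "GFP", channel_index = 1L,
                       pixel_size = NULL,
                       threshold_method = c("otsu", "fixed"),
                       threshold_value = NULL,
                       min_hole = 64, min_object = 4,
                       ellipse_mode = c("auto", "manual"),
                       min_area_px2 = 10, h_min_px = 5,
                       distance_mode = c("centroid", "nearest_pixel"),
                       tissue_channel = NULL, tissue_threshold = 20,
                       brain_map = NULL, qc = FALSE) {
  threshold_method <- match.arg(threshold_method)
  ellipse_mode <- match.arg(ellipse_mode)
  distance_mode <- match.arg(distance_mode)
  if (!is.character(input) || length(input) == 0L)
    stop("config field `input`: supply at least one path or glob")
  if (!is.character(out_dir) || length(out_dir) != 1L)
    stop("config field `out_dir`: supply a single output directory")
  if (threshold_method == "fixed" && is.null(threshold_value))
    stop("config field `threshold_value`: required when threshold_method = 'fixed'")
  if (!is.null(pixel_size) && (!is.numeric(pixel_size) || pixel_size <= 0))
    stop("config field `pixel_size`: must be > 0 (um/px)")
  if (min_area_px2 < 0) stop("config field `min_area_px2`: must be >= 0")
  if (h_min_px < 0) stop("config field `h_min_px`: must be >= 0")
  if (min_hole < 0 || min_object < 0)
    stop("config fields `min_hole`/`min_object`: must be >= 0")
  if (!is.null(brain_map) &&
      (is.null(names(brain_map)) || any(names(brain_map) == "")))
    stop("config field `brain_map`: must be a fully named character vector")
  structure(list(
    input = input, out_dir = out_dir, channel = channel,
    channel_index = as.integer(channel_index), pixel_size = pixel_size,
    threshold_method = threshold_method, threshold_value = threshold_value,
    min_hole = min_hole, min_object = min_object,
    ellipse_mode = ellipse_mode, min_area_px2 = min_area_px2,
    h_min_px = h_min_px, distance_mode = distance_mode,
    tissue_channel = tissue_channel, tissue_threshold = tissue_threshold,
    brain_map = brain_map, qc = isTRUE(qc)
  ), class = "run_config")
}

image_id_for <- function(path) {
  base <- tools::file_path_sans_ext(basename(path))
  paste(basename(dirname(path)), base, sep = "/")
}

#' Run the full invasion pipeline on one image
#'
#' Segmentation, core-ellipse delimitation, core subtraction, watershed
#' splitting, size filtering, per-particle measurement and per-image summary,
#' in that order.
#'
#' @param path A TIFF path (readable by [read_stack()]).
#' @param config A [run_config()] (the `input`/`out_dir` fields are unused
#'   here).
#' @return List with `image_id`, `table` ([measure_particles()] output),
#'   `metrics` ([summarize_invasion()]), `ell`, `mask` (cleaned full mask),
#'   `image8` (8-bit tumour channel).
#' @export
process_image <- function(path, config) {
  stopifnot(inherits(config, "run_config"))
  stack <- read_stack(path, pixel_size = config$pixel_size)
  img <- if (!is.null(config$channel) && config$channel %in% names(stack))
    select_channel(stack, name = config$channel)
  else select_channel(stack, index = config$channel_index)
  img8 <- to_8bit(img)
  mask <- binarize(img8, method = config$threshold_method,
                   threshold = config$threshold_value)
  mask <- clean_mask(mask, min_hole = config$min_hole,
                     min_object = config$min_object)
  ell <- if (config$ellipse_mode == "manual") {
    ep <- paste0(path, ".ellipse.json")
    if (!file.exists(ep))
      stop("manual ellipse mode: missing sidecar ", ep)
    e <- jsonlite::read_json(ep, simplifyVector = TRUE)
    theta <- if (!is.null(e$theta_deg)) e$theta_deg * pi / 180 else e$theta
    ellipse(e$cx, e$cy, e$a, e$b, theta)
  } else {
    fit_core_ellipse(mask)
  }
  invasive <- subtract_core(mask, ell)
  labels <- split_particles(invasive, h_min = config$h_min_px)
  labels <- filter_particles(labels, min_area = config$min_area_px2)
  table <- measure_particles(labels, ell, pixel_size = img$pixel_size,
                             distance_mode = config$distance_mode)
  pct <- NULL
  if (!is.null(config$tissue_channel) &&
      config$tissue_channel %in% names(stack) && any(mask)) {
    tmask <- select_channel(stack, config$tissue_channel)$pixels >
      config$tissue_threshold
    pct <- pct_within_slice(mask, tissue_mask = tmask)
  }
  list(image_id = image_id_for(path), table = table,
       metrics = summarize_invasion(table, pct_within = pct),
       ell = ell, mask = mask, labels = labels, image8 = img8)
}

#' Run the pipeline over a batch of images and aggregate replicates
#'
#' Processes every resolved input (a failing image is reported and skipped,
#' not fatal), writes per-image particle CSVs and metrics JSONs, a combined
#' per-image metrics CSV, per-brain and group aggregate CSVs, optional QC
#' overlays, and a manifest echoing the configuration and software version.
#' Output is deterministic: identical inputs and configuration produce
#' byte-identical combined CSVs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `combined` (per-image metrics
#'   `data.frame`), `aggregate` ([aggregate_replicates()] output or `NULL`),
#'   `n_failed`, and `paths` of the files written.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- unique(unlist(lapply(config$input, function(p)
    if (file.exists(p) && !dir.exists(p)) p else Sys.glob(p))))
  paths <- sort(paths)
  if (length(paths) == 0L)
    stop("configuration error: no input images resolved from ",
         paste(config$input, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  rows <- list(); failures <- character(0L)
  for (p in paths) {
    res <- tryCatch(process_image(p, config), error = function(e) e)
    id <- image_id_for(p)
    if (inherits(res, "error")) {
      message("[spherinv] FAILED ", id, ": ", conditionMessage(res))
      failures <- c(failures, id)
      next
    }
    safe <- gsub("[^A-Za-z0-9_.-]", "_", id)
    write_results(res$table, res$metrics,
                  file.path(config$out_dir, paste0(safe, "_particles.csv")))
    if (config$qc)
      qc_overlay(res$image8, res$ell, res$labels,
                 file.path(config$out_dir, paste0(safe, "_qc.png")))
    m <- res$metrics
    brain <- if (!is.null(config$brain_map) && id %in% names(config$brain_map))
      unname(config$brain_map[[id]]) else id
    rows[[id]] <- data.frame(
      image_id = id, brain_id = brain, n_particles = m$n_particles,
      invasive_area_px2 = m$invasive_area_px2,
      invasive_area_um2 = m$invasive_area_um2,
      mean_distance_px = m$mean_distance_px,
      mean_distance_um = m$mean_distance_um,
      max_distance_px = m$max_distance_px,
      max_distance_um = m$max_distance_um,
      pct_within_slice = m$pct_within_slice
    )
  }
  if (length(rows) == 0L)
    stop("all ", length(paths), " image(s) failed: ",
         paste(failures, collapse = ", "))
  combined <- do.call(rbind, rows)
  rownames(combined) <- NULL
  combined_path <- file.path(config$out_dir, "combined_metrics.csv")
  write.csv(combined, combined_path, row.names = FALSE)

  agg <- aggregate_replicates(combined)
  write.csv(agg$per_brain, file.path(config$out_dir, "per_brain.csv"),
            row.names = FALSE)
  write.csv(agg$group, file.path(config$out_dir, "group_summary.csv"),
            row.names = FALSE)

  manifest <- list(
    package = "spherinv",
    version = as.character(utils::packageVersion("spherinv")),
    config = unclass(config),
    n_images = length(paths), n_processed = nrow(combined),
    failed = failures
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(combined = combined, aggregate = agg,
                 n_failed = length(failures),
                 paths = list(combined = combined_path,
                              out_dir = config$out_dir)))
}

#' Write a QC overlay PNG
#'
#' Grayscale tumour channel with the core ellipse drawn in red and particle
#' outlines in yellow.
#'
#' @param image8 8-bit [calibrated_image()] (e.g. from [to_8bit()]).
#' @param ell A [ellipse()].
#' @param labels Integer particle label matrix (same size).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
qc_overlay <- function(image8, ell, labels, path) {
  px <- image8$pixels / 255
  h <- nrow(px); w <- ncol(px)
  rgb <- array(rep(px, 3L), dim = c(h, w, 3L))
  # ellipse boundary, parametric sampling at sub-pixel step
  tt <- seq(0, 2 * pi, length.out = max(720L, ceiling(8 * pi * ell$a)))
  bx <- ell$cx + ell$a * cos(tt) * cos(ell$theta) -
    ell$b * sin(tt) * sin(ell$theta)
  by <- ell$cy + ell$a * cos(tt) * sin(ell$theta) +
    ell$b * sin(tt) * cos(ell$theta)
  keep <- bx >= 1 & bx <= w & by >= 1 & by <= h
  bi <- cbind(round(by[keep]), round(bx[keep]))
  rgb[cbind(bi, 1L)] <- 1; rgb[cbind(bi, 2L)] <- 0; rgb[cbind(bi, 3L)] <- 0
  # particle outlines: foreground pixels with a 4-neighbour background
  fg <- labels > 0L
  if (any(fg)) {
    pad <- rbind(FALSE, cbind(FALSE, fg, FALSE), FALSE)
    core4 <- pad[2:(h + 1), 2:(w + 1)] & pad[1:h, 2:(w + 1)] &
      pad[3:(h + 2), 2:(w + 1)] & pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
    edge <- which(fg & !core4, arr.ind = TRUE)
    rgb[cbind(edge, 1L)] <- 1; rgb[cbind(edge, 2L)] <- 1
    rgb[cbind(edge, 3L)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
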