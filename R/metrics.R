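#' Summarize a particle table into invasion statistics
#'
#' The three per-image invasion statistics: (1) invasive-edge area, the sum
#' of the areas of all retained particles outside the core ellipse; (2) mean
#' distance, the unweighted average of the per-particle distances to the
#' nearest edge of the ellipse; (3) maximum distance, the greatest such
#' distance. An empty table yields zero area, zero particles, and `NA`
#' distances.
#'
#' @param table A particle table from [measure_particles()].
#' @param pct_within Optional percentage of the spheroid within the slice
#'   (see [pct_within_slice()]), carried through to the output.
#' @return An object of class `invasion_metrics`: a list with
#'   `n_particles`, `invasive_area_px2`, `invasive_area_um2`,
#'   `mean_distance_px`, `mean_distance_um`, `max_distance_px`,
#'   `max_distance_um`, `pct_within_slice`.
#' @export
summarize_invasion <- function(table, pct_within = NULL) {
  stopifnot(is.data.frame(table))
  n <- nrow(table)
  calibrated <- n > 0L && all(!is.na(table$area_um2))
  m <- list(
    n_particles = n,
    invasive_area_px2 = if (n) sum(table$area_px2) else 0,
    invasive_area_um2 = if (n && calibrated) sum(table$area_um2)
                        else if (n) NA_real_ else 0,
    mean_distance_px = if (n) mean(table$distance_px) else NA_real_,
    mean_distance_um = if (n && calibrated) mean(table$distance_um) else NA_real_,
    max_distance_px = if (n) max(table$distance_px) else NA_real_,
    max_distance_um = if (n && calibrated) max(table$distance_um) else NA_real_,
    pct_within_slice = if (is.null(pct_within)) NA_real_ else as.numeric(pct_within)
  )
  structure(m, class = "invasion_metrics")
}

#' @export
print.invasion_metrics <- function(x, ...) {
  cat(sprintf("invasion_metrics: %d particle(s), invasive area %.1f px^2\n",
              x$n_particles, x$invasive_area_px2))
  if (x$n_particles > 0)
    cat(sprintf("  distance to ellipse edge: mean %.2f px, max %.2f px\n",
                x$mean_distance_px, x$max_distance_px))
  if (!is.na(x$pct_within_slice))
    cat(sprintf("  %.1f%% of spheroid within slice\n", x$pct_within_slice))
  invisible(x)
}

#' Percentage of the spheroid lying within the brain slice
#'
#' In a Z-section the slice surface appears as a roughly horizontal line;
#' spheroid area below it (larger y, image origin top-left) is inside the
#' slice. Supply either the surface line directly or a tissue-channel mask,
#' from which the line is estimated as the median over columns of the
#' topmost tissue foreground row.
#'
#' @param spheroid_mask Logical matrix of the spheroid (non-empty).
#' @param surface_line Surface y-coordinate, px.
#' @param tissue_mask Logical tissue-channel mask (alternative to
#'   `surface_line`; supply exactly one).
#' @return Percentage in `[0, 100]`.
#' @export
pct_within_slice <- function(spheroid_mask, surface_line = NULL,
                             tissue_mask = NULL) {
  stopifnot(is.matrix(spheroid_mask), is.logical(spheroid_mask))
  if (!any(spheroid_mask)) stop("no spheroid: mask is empty")
  if (is.null(surface_line) == is.null(tissue_mask))
    stop("supply exactly one of `surface_line` or `tissue_mask`")
  if (is.null(surface_line)) {
    stopifnot(is.matrix(tissue_mask), is.logical(tissue_mask))
    tops <- apply(tissue_mask, 2L, function(col) {
      w <- which(col)
      if (length(w)) w[1L] else NA_integer_
    })
    if (all(is.na(tops))) stop("tissue mask is empty; cannot locate surface")
    surface_line <- median(tops, na.rm = TRUE)
  }
  rows <- which(spheroid_mask, arr.ind = TRUE)[, 1L]
  100 * sum(rows >= surface_line) / length(rows)
}

#' Aggregate per-image metrics into per-brain and group summaries
#'
#' Images of the same brain are technical replicates: averaging them yields
#' one value per brain (the biological replicate); the group summary is the
#' mean and standard deviation (n - 1 denominator) across brains.
#'
#' @param per_image A `data.frame` with a `brain_id` column plus numeric
#'   metric columns (e.g. as built by [run_batch()]: `invasive_area_px2`,
#'   `mean_distance_px`, ...). Non-numeric columns other than `brain_id` are
#'   ignored.
#' @return A list with `per_brain` (one row per brain, mean of each metric,
#'   plus `n_images`) and `group` (one row per metric: `mean`, `sd`,
#'   `n_brains`).
#' @export
aggregate_replicates <- function(per_image) {
  stopifnot(is.data.frame(per_image), "brain_id" %in% names(per_image))
  if (nrow(per_image) == 0L) stop("no images to aggregate")
  num <- vapply(per_image, is.numeric, logical(1L))
  metrics <- setdiff(names(per_image)[num], "brain_id")
  if (!length(metrics)) stop("no numeric metric columns to aggregate")
  ids <- sort(unique(as.character(per_image$brain_id)))
  per_brain <- do.call(rbind, lapply(ids, function(id) {
    rows <- per_image[as.character(per_image$brain_id) == id, , drop = FALSE]
    vals <- vapply(metrics, function(mcol) mean(rows[[mcol]], na.rm = TRUE),
                   numeric(1L))
    cbind(data.frame(brain_id = id, n_images = nrow(rows)),
          as.data.frame(as.list(vals)))
  }))
  group <- do.call(rbind, lapply(metrics, function(mcol) {
    v <- per_brain[[mcol]]
    data.frame(metric = mcol, mean = mean(v, na.rm = TRUE),
               sd = if (sum(!is.na(v)) > 1L) sd(v, na.rm = TRUE) else NA_real_,
               n_brains = sum(!is.na(v)))
  }))
  rownames(per_brain) <- NULL
  rownames(group) <- NULL
  list(per_brain = per_brain, group = group)
}
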