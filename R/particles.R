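#' Test whether pixel centres lie inside or on the core ellipse
#'
#' @param x,y Coordinate vectors, px.
#' @param ell A [ellipse()].
#' @param tol Tolerance on the canonical quadratic form for "on the edge".
#' @return Logical vector.
#' @export
inside_ellipse <- function(x, y, ell, tol = 1e-12) {
  ct <- cos(ell$theta); st <- sin(ell$theta)
  dx <- x - ell$cx; dy <- y - ell$cy
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  (u / ell$a)^2 + (v / ell$b)^2 <= 1 + tol
}

#' Subtract the spheroid core from the mask
#'
#' Clears every foreground pixel whose centre lies inside or on the core
#' ellipse; everything else is preserved. What remains is the invasive
#' material outside the core (including any rim fragments the ellipse did
#' not cover — those are legitimate particles, subject to the size filter).
#'
#' @param mask Logical matrix.
#' @param ell A [ellipse()].
#' @return Logical matrix.
#' @export
subtract_core <- function(mask, ell) {
  stopifnot(is.matrix(mask), is.logical(mask), inherits(ell, "core_ellipse"))
  out <- mask
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg)) {
    inside <- inside_ellipse(fg[, 2L], fg[, 1L], ell)
    out[fg[inside, , drop = FALSE]] <- FALSE
  }
  out
}

#' Label invasive particles, splitting touching blobs by watershed
#'
#' Connected components are labelled 8-connected; components containing
#' several peaks of the Euclidean distance transform are split by watershed
#' flooding of the negated distance transform. Peaks shallower than `h_min`
#' relative to their saddle are merged into their neighbour, so a lone
#' convex blob is never split. Every foreground pixel receives exactly one
#' label; labels are compacted to `1..n` in raster order.
#'
#' @param mask Logical matrix (post core subtraction).
#' @param h_min Minimum peak depth (px) for a distance-transform maximum to
#'   seed its own particle.
#' @return Integer label matrix (0 = background).
#' @export
split_particles <- function(mask, h_min = 5) {
  stopifnot(is.matrix(mask), is.logical(mask), h_min >= 0)
  if (!any(mask)) return(array(0L, dim(mask)))
  dm <- EBImage::distmap(mask, metric = "euclidean")
  ws <- EBImage::watershed(dm, tolerance = h_min, ext = 1)
  lab <- matrix(as.integer(ws), nrow = nrow(mask))
  if (!identical(lab > 0L, unname(mask)))
    stop("internal error: watershed changed the foreground")  # nocov
  compact_labels(lab)
}

#' Filter particles by the minimum-size rule
#'
#' Retains particles whose area is strictly greater than `min_area` px^2
#' (the default reproduces the "greater than 10 px^2" rule used to define a
#' reportable particle) and recompacts labels to `1..n`.
#'
#' @param labels Integer label matrix.
#' @param min_area Strict lower bound on particle area, px^2.
#' @return Integer label matrix.
#' @export
filter_particles <- function(labels, min_area = 10) {
  stopifnot(is.matrix(labels), min_area >= 0)
  if (max(labels) == 0L) return(array(0L, dim(labels)))
  sizes <- component_sizes(labels)
  drop <- which(sizes <= min_area)
  out <- labels
  if (length(drop)) out[out %in% drop] <- 0L
  compact_labels(out)
}

#' Measure invasive particles against the core ellipse
#'
#' Per particle: area (pixel count, px^2, and um^2 when calibrated), centroid
#' (mean of pixel centre coordinates) and distance to the nearest point of
#' the ellipse edge. `distance_mode = "centroid"` evaluates the distance at
#' the particle centroid (one stable summary point per particle, the
#' default); `"nearest_pixel"` takes the minimum over all the particle's
#' pixel centres, which is never larger.
#'
#' @param labels Integer label matrix.
#' @param ell A [ellipse()].
#' @param pixel_size Micrometres per pixel, or `NULL` for pixel-only output.
#' @param distance_mode `"centroid"` or `"nearest_pixel"`.
#' @return A `data.frame` with columns `label`, `area_px2`, `area_um2`,
#'   `centroid_x`, `centroid_y`, `distance_px`, `distance_um` (`area_um2` /
#'   `distance_um` are `NA` when uncalibrated), one row per particle,
#'   ordered by label.
#' @export
measure_particles <- function(labels, ell, pixel_size = NULL,
                              distance_mode = c("centroid", "nearest_pixel")) {
  stopifnot(is.matrix(labels), inherits(ell, "core_ellipse"))
  distance_mode <- match.arg(distance_mode)
  n <- max(labels)
  if (n == 0L) return(empty_particle_table())
  idx <- which(labels > 0L, arr.ind = TRUE)
  lb <- labels[labels > 0L]
  area <- tabulate(lb, nbins = n)
  cx <- vapply(split(idx[, 2L], lb), mean, numeric(1L))
  cy <- vapply(split(idx[, 1L], lb), mean, numeric(1L))
  dist <- if (distance_mode == "centroid") {
    edge_distances(cx, cy, ell)
  } else {
    pix_d <- edge_distances(idx[, 2L], idx[, 1L], ell)
    vapply(split(pix_d, lb), min, numeric(1L))
  }
  data.frame(
    label = seq_len(n),
    area_px2 = as.numeric(area),
    area_um2 = if (is.null(pixel_size)) NA_real_ else area * pixel_size^2,
    centroid_x = unname(cx),
    centroid_y = unname(cy),
    distance_px = unname(dist),
    distance_um = if (is.null(pixel_size)) NA_real_ else unname(dist) * pixel_size
  )
}

empty_particle_table <- function() {
  data.frame(label = integer(0L), area_px2 = numeric(0L),
             area_um2 = numeric(0L), centroid_x = numeric(0L),
             centroid_y = numeric(0L), distance_px = numeric(0L),
             distance_um = numeric(0L))
}
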