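#' Binarize the tumour channel
#'
#' Produces the binary mask used for core delimitation and particle analysis.
#' With `method = "otsu"` the image is first rendered to 8-bit (as in the
#' convert-then-mask workflow) and the threshold is found by exhaustive
#' maximization of the between-class variance over all 256 histogram bins;
#' ties are broken towards the lowest threshold. With `method = "fixed"` the
#' supplied threshold is applied to the image's own intensity scale.
#' Foreground is strictly above the threshold in both cases.
#'
#' @param image A [calibrated_image()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Required for `method = "fixed"`.
#' @return Logical matrix mask (`TRUE` = foreground).
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(threshold)) stop("method = 'fixed' requires `threshold`")
    return(image$pixels > threshold)
  }
  rng <- range(image$pixels)
  if (rng[1L] == rng[2L])
    stop("degenerate input: constant image has no Otsu threshold; ",
         "use method = 'fixed'")
  px8 <- to_8bit(image)$pixels
  thr <- otsu_threshold(tabulate(as.integer(px8) + 1L, nbins = 256L))
  px8 > thr
}

#' Exhaustive Otsu threshold from a 256-bin histogram
#'
#' Scans every candidate threshold `k = 0..254` (foreground = bins above `k`)
#' and returns the one maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. The lowest maximizing `k` wins on ties.
#'
#' @param counts Integer vector of length 256: pixel counts per intensity.
#' @return The threshold `k` (intensity value, 0-based).
#' @export
otsu_threshold <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty histogram")
  lev <- 0:255
  w0 <- cumsum(counts)[1:255]          # background: bins 0..k
  w1 <- n - w0
  s0 <- cumsum(counts * lev)[1:255]
  stot <- sum(counts * lev)
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (stot - s0) / w1, 0)
  bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  if (all(!is.finite(bcv)))
    stop("degenerate histogram: all pixels in one bin")
  which.max(bcv) - 1L                  # which.max takes the first maximum
}

#' Clean a binary mask before ellipse fitting and particle analysis
#'
#' Fills holes (8-connected background components not touching the image
#' border) smaller than `min_hole` and removes foreground objects smaller
#' than `min_object`. Defaults stay below the 10 px^2 particle-size filter
#' so cleaning can never delete a reportable particle.
#'
#' @param mask Logical matrix.
#' @param min_hole Holes strictly smaller than this (px^2) are filled.
#' @param min_object Objects strictly smaller than this (px^2) are removed.
#' @return Cleaned logical matrix.
#' @export
clean_mask <- function(mask, min_hole = 64, min_object = 4) {
  stopifnot(is.matrix(mask), is.logical(mask), min_hole >= 0, min_object >= 0)
  out <- mask
  if (min_hole > 0 && any(!out)) {
    bg <- label_components(!out)
    if (max(bg) > 0L) {
      border_ids <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
      sizes <- component_sizes(bg)
      fill <- setdiff(which(sizes < min_hole), border_ids)
      if (length(fill)) out[bg %in% fill] <- TRUE
    }
  }
  if (min_object > 0 && any(out)) {
    fgl <- label_components(out)
    sizes <- component_sizes(fgl)
    drop <- which(sizes < min_object)
    if (length(drop)) out[fgl %in% drop] <- FALSE
  }
  out
}

#' Ellipse delimiting the spheroid core
#'
#' Constructs (and validates) the ellipse used to delimit the dense spheroid
#' core — either from an automatic fit ([fit_core_ellipse()]) or supplied
#' manually, mirroring the interactive adjust-the-ellipse step of the
#' original workflow. `theta` is normalized into `[0, pi)` (an ellipse is
#' symmetric under rotation by pi).
#'
#' @param cx,cy Centre, px (image coordinates, x = column, y = row).
#' @param a,b Semi-major and semi-minor axes, px; requires `a >= b > 0`.
#' @param theta Rotation of the major axis, radians, from +x towards +y.
#' @return An object of class `core_ellipse`.
#' @export
ellipse <- function(cx, cy, a, b, theta = 0) {
  vals <- c(cx = cx, cy = cy, a = a, b = b, theta = theta)
  if (!all(is.finite(vals))) stop("ellipse parameters must be finite")
  if (b <= 0) stop("axes must be positive (b > 0)")
  if (a < b) stop("axes must satisfy a >= b")
  theta <- theta %% pi
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 a = as.numeric(a), b = as.numeric(b),
                 theta = as.numeric(theta)),
            class = "core_ellipse")
}

#' @export
print.core_ellipse <- function(x, ...) {
  cat(sprintf(
    "core_ellipse: centre (%.2f, %.2f), a = %.2f px, b = %.2f px, theta = %.1f deg\n",
    x$cx, x$cy, x$a, x$b, x$theta * 180 / pi))
  invisible(x)
}

#' Fit the core ellipse to the largest mask component
#'
#' Selects the largest 8-connected foreground component and returns the
#' ellipse with the same zeroth and second central moments (the classic
#' moments-of-inertia fit): semi-axes `2 * sqrt(eigenvalue)` of the pixel
#' covariance (with the 1/12 per-pixel square correction), orientation from
#' the principal eigenvector. For convex rendered shapes `pi * a * b`
#' approximates the component's pixel area.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return A [ellipse()] object.
#' @export
fit_core_ellipse <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("no core found: mask is empty")
  lab <- label_components(mask)
  sizes <- component_sizes(lab)
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  y <- idx[, 1L]; x <- idx[, 2L]
  cx <- mean(x); cy <- mean(y)
  # second central moments; +1/12 accounts for each pixel being a unit square
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  eg <- eigen(matrix(c(mxx, mxy, mxy, myy), 2L, 2L), symmetric = TRUE)
  a <- 2 * sqrt(eg$values[1L])
  b <- 2 * sqrt(max(eg$values[2L], 1e-12))
  v <- eg$vectors[, 1L]
  ellipse(cx, cy, a, b, atan2(v[2L], v[1L]))
}
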