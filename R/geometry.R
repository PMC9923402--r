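#' Exact distance from a point to the edge of the core ellipse
#'
#' Computes the minimum Euclidean distance from an arbitrary point (inside or
#' outside) to the ellipse boundary, together with the nearest boundary
#' point. The point is moved into the ellipse's canonical frame (centre at
#' the origin, axes on the coordinate axes) and, by symmetry, into the first
#' quadrant; there the squared distance to the boundary parameterized as
#' `(a cos t, b sin t)` is unimodal on `t in [0, pi/2]` and is minimized by
#' golden-section/parabolic bracketing followed by Newton polishing of the
#' stationarity condition (parameter tolerance 1e-10). Distances are
#' signless: the interior of the core carries no negative sign.
#'
#' @param x,y Point coordinates, px (image frame).
#' @param ell A [ellipse()].
#' @return A list with `value` (distance, px, >= 0) and `nearest_point`
#'   (`c(x, y)` on the boundary).
#' @export
distance_to_edge <- function(x, y, ell) {
  stopifnot(inherits(ell, "core_ellipse"), is.finite(x), is.finite(y))
  ct <- cos(ell$theta); st <- sin(ell$theta)
  dx <- x - ell$cx; dy <- y - ell$cy
  u <- ct * dx + st * dy
  v <- -st * dx + ct * dy
  sol <- edge_solve_quadrant(abs(u), abs(v), ell$a, ell$b)
  nu <- sol$bx * sign_pos(u)
  nv <- sol$by * sign_pos(v)
  nearest <- c(x = ell$cx + ct * nu - st * nv,
               y = ell$cy + st * nu + ct * nv)
  list(value = sol$dist, nearest_point = nearest)
}

sign_pos <- function(z) if (z >= 0) 1 else -1

# First-quadrant solve: point (u, v) with u, v >= 0, ellipse x^2/a^2 +
# y^2/b^2 = 1. Returns distance and boundary point (bx, by).
edge_solve_quadrant <- function(u, v, a, b) {
  f <- function(t) (a * cos(t) - u)^2 + (b * sin(t) - v)^2
  t <- optimize(f, c(0, pi / 2), tol = 1e-12)$minimum
  # Newton polish of g(t) = f'(t)/2; keeps t in [0, pi/2]
  for (i in 1:4) {
    ct <- cos(t); st <- sin(t)
    g <- (a * ct - u) * (-a * st) + (b * st - v) * (b * ct)
    gp <- a^2 * st^2 - a * ct * (a * ct - u) +
          b^2 * ct^2 - b * st * (b * st - v)
    if (!is.finite(gp) || abs(gp) < 1e-300) break
    tn <- t - g / gp
    if (!is.finite(tn)) break
    tn <- min(max(tn, 0), pi / 2)
    if (abs(tn - t) < 1e-14) { t <- tn; break }
    t <- tn
  }
  # endpoints can beat the interior stationary point (e.g. points on an axis)
  cand <- unique(c(t, 0, pi / 2))
  fc <- vapply(cand, f, numeric(1L))
  t <- cand[which.min(fc)]
  list(dist = sqrt(min(fc)), bx = a * cos(t), by = b * sin(t))
}

#' Vectorized edge distances
#'
#' Applies [distance_to_edge()] to paired coordinate vectors and returns the
#' distances only.
#'
#' @param x,y Equal-length coordinate vectors, px.
#' @param ell A [ellipse()].
#' @return Numeric vector of distances, px.
#' @export
edge_distances <- function(x, y, ell) {
  stopifnot(length(x) == length(y))
  vapply(seq_along(x),
         function(i) distance_to_edge(x[i], y[i], ell)$value,
         numeric(1L))
}

#' Per-pixel distance map to the ellipse edge
#'
#' Evaluates [distance_to_edge()] at every pixel centre. Intended for QC
#' visualization (the colour-map step of the original workflow); particle
#' statistics use the exact per-particle distances instead.
#'
#' @param shape `c(height, width)` in px.
#' @param ell A [ellipse()].
#' @return Numeric `height x width` matrix of distances, px.
#' @export
edge_distance_map <- function(shape, ell) {
  stopifnot(length(shape) == 2L, all(shape >= 1))
  h <- shape[1L]; w <- shape[2L]
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  matrix(edge_distances(xs, ys, ell), nrow = h, ncol = w)
}
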