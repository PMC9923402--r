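# Shared fixtures and independent oracles, built in code.

# disk mask with pixel-centre rasterization
disk_mask <- function(h, w, cx, cy, r) {
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  matrix((xs - cx)^2 + (ys - cy)^2 <= r^2, nrow = h, ncol = w)
}

# filled rotated-ellipse mask (independent of inside_ellipse: explicit algebra)
ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  xs <- rep(seq_len(w), each = h) - cx
  ys <- rep(seq_len(h), times = w) - cy
  u <- cos(theta) * xs + sin(theta) * ys
  v <- -sin(theta) * xs + cos(theta) * ys
  matrix((u / a)^2 + (v / b)^2 <= 1, nrow = h, ncol = w)
}

# naive Otsu oracle: for every threshold k, recompute class weights and means
# from the raw pixel subsets and maximize the between-class variance
otsu_oracle <- function(px8) {
  v <- as.vector(px8)
  n <- length(v)
  best_k <- NA_integer_; best <- -Inf
  for (k in 0:254) {
    lo <- v[v <= k]; hi <- v[v > k]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) { best <- bcv; best_k <- k }
  }
  best_k
}

# dense boundary-sampling oracle for point-to-ellipse distance
edge_dist_oracle <- function(x, y, ell, n = 1e5) {
  tg <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  bx <- ell$cx + ell$a * cos(tg) * cos(ell$theta) -
    ell$b * sin(tg) * sin(ell$theta)
  by <- ell$cy + ell$a * cos(tg) * sin(ell$theta) +
    ell$b * sin(tg) * cos(ell$theta)
  sqrt(min((bx - x)^2 + (by - y)^2))
}

# a small, fast scene for routine tests
small_scene_params <- function(...) {
  defaults <- list(
    width = 256, height = 256,
    core = list(cx = 128, cy = 128, a = 45, b = 30, theta = pi / 6),
    n_single_cells = 8, n_strands = 3,
    core_clearance = c(6, 50), noise_sd = 0)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

# run the measurement pipeline on a scene against a given (usually truth) core
recover_particles <- function(scene, ell = scene$truth_core,
                              min_area = 10, h_min = 5) {
  img8 <- to_8bit(select_channel(scene$stack, "GFP"))
  mask <- clean_mask(binarize(img8, "otsu"))
  inv <- subtract_core(mask, ell)
  lab <- filter_particles(split_particles(inv, h_min = h_min),
                          min_area = min_area)
  list(mask = mask, labels = lab,
       table = measure_particles(lab, ell, scene$params$pixel_size))
}
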