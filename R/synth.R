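#' Parameters for a synthetic Z-section scene
#'
#' Describes a two-channel synthetic micrograph emulating a re-sectioned
#' brain slice bearing an implanted tumour spheroid: a bright elliptical
#' core, round single-cell blobs and elongated strand-like blobs invading
#' outward, a dimmer textured tissue channel with a flat surface line, and
#' additive Gaussian noise.
#'
#' @param width,height Image size, px.
#' @param core Core ellipse as `list(cx, cy, a, b, theta)`.
#' @param n_single_cells Number of round invading cells.
#' @param n_strands Number of elongated strand-like particles, oriented
#'   roughly radially.
#' @param n_touching_pairs Number of deliberately overlapping cell pairs
#'   (each pair is one connected blob with two distance peaks, for
#'   watershed testing).
#' @param n_straddling Number of blobs planted straddling the core edge.
#' @param cell_radius Radius range for single cells, px.
#' @param strand_length,strand_width Length and width ranges for strands, px.
#' @param core_clearance Range of particle-centre distances from the core
#'   edge, px.
#' @param touch_radius,touch_sep Radius and centre separation of touching
#'   pairs, px (`touch_sep < 2 * touch_radius` so the pair overlaps).
#' @param submergence Target fraction of spheroid area below the slice
#'   surface, in `[0, 1]`.
#' @param background,core_intensity,cell_intensity,strand_intensity,tissue_level
#'   Mean intensities (arbitrary camera units).
#' @param noise_sd Additive Gaussian noise SD on the tumour channel;
#'   the tissue texture SD is fixed at 8.
#' @param min_gap Minimum separation between rendered objects, px.
#' @param pixel_size Micrometres per pixel recorded in the scene.
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   scene bit-exactly.
#' @return A `scene_params` list.
#' @export
scene_params <- function(width = 384, height = 384,
                         core = list(cx = width / 2, cy = height / 2,
                                     a = 70, b = 45, theta = pi / 6),
                         n_single_cells = 12, n_strands = 5,
                         n_touching_pairs = 0, n_straddling = 0,
                         cell_radius = c(2.5, 5),
                         strand_length = c(15, 40), strand_width = c(3, 5),
                         core_clearance = c(8, 80),
                         touch_radius = 16, touch_sep = 24,
                         submergence = 1,
                         background = 8, core_intensity = 220,
                         cell_intensity = 180, strand_intensity = 160,
                         tissue_level = 40, noise_sd = 5,
                         min_gap = 2, pixel_size = 0.65, seed = 1) {
  p <- as.list(environment())
  stopifnot(width >= 32, height >= 32,
            n_single_cells >= 0, n_strands >= 0, n_touching_pairs >= 0,
            n_straddling >= 0,
            all(cell_radius > 0), all(strand_length > 0),
            all(strand_width > 0), all(core_clearance >= 0),
            submergence >= 0, submergence <= 1, noise_sd >= 0)
  structure(p, class = "scene_params")
}

# pixel-centre disk footprint as a full-size logical matrix
render_disk <- function(h, w, cx, cy, r) {
  out <- matrix(FALSE, h, w)
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(out)
  sub <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  out[ys, xs] <- sub
  out
}

# capsule (thick segment) footprint: pixel centres within halfw of the segment
render_capsule <- function(h, w, x1, y1, x2, y2, halfw) {
  out <- matrix(FALSE, h, w)
  ys <- max(1L, floor(min(y1, y2) - halfw)):min(h, ceiling(max(y1, y2) + halfw))
  xs <- max(1L, floor(min(x1, x2) - halfw)):min(w, ceiling(max(x1, x2) + halfw))
  if (!length(ys) || !length(xs)) return(out)
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- if (len2 > 0) pmin(pmax(((px - x1) * vx + (py - y1) * vy) / len2, 0), 1) else 0
  d2 <- (px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2
  out[ys, xs] <- matrix(d2 <= halfw^2, length(ys), length(xs))
  out
}

# radius of the ellipse boundary along direction phi (world frame)
boundary_radius <- function(ell, phi) {
  psi <- phi - ell$theta
  1 / sqrt((cos(psi) / ell$a)^2 + (sin(psi) / ell$b)^2)
}

#' Generate a synthetic scene with exact ground truth
#'
#' Renders the scene described by [scene_params()] and returns it with
#' pixel-exact ground truth: the core ellipse, the particle label image,
#' the particle table (rendered pixel counts, centroids, centroid-mode edge
#' distances), and the achieved percentage of spheroid within the slice.
#' Particles are placed by rejection sampling so that they never touch the
#' core or each other (straddling blobs excepted, by design). The RNG state
#' is restored on exit.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `synth_scene`: list with `stack`,
#'   `truth_core`, `truth_labels`, `truth_table`, `truth_pct_within`,
#'   `surface_line`, `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(params$seed)
  h <- params$height; w <- params$width
  core <- ellipse(params$core$cx, params$core$cy, params$core$a,
                  params$core$b, params$core$theta)

  core_mask <- matrix(inside_ellipse(rep(seq_len(w), each = h),
                                     rep(seq_len(h), times = w), core),
                      nrow = h, ncol = w)
  brush <- EBImage::makeBrush(2L * ceiling(params$min_gap) + 1L, "disc")
  occupied <- matrix(EBImage::dilate(core_mask, brush) > 0, h, w)
  occupied_particles <- matrix(FALSE, h, w)   # excludes the core clearance ring

  labels <- matrix(0L, h, w)
  n_lab <- 0L
  objects <- list()   # footprints with their rendering intensity
  place <- function(render_fn, intensity) {
    for (try in 1:200) {
      fp <- render_fn()
      if (!any(fp)) next
      edge_touch <- any(fp[1L, ]) || any(fp[h, ]) || any(fp[, 1L]) || any(fp[, w])
      if (edge_touch || any(fp & occupied)) next
      n_lab <<- n_lab + 1L
      labels[fp] <<- n_lab
      objects[[length(objects) + 1L]] <<- list(fp = fp, intensity = intensity)
      grown <- matrix(EBImage::dilate(fp, brush) > 0, h, w)
      occupied <<- occupied | grown
      occupied_particles <<- occupied_particles | grown
      return(invisible(TRUE))
    }
    stop("particle placement failed after 200 attempts; ",
         "use fewer or smaller particles")
  }
  sample_centre <- function(extent) {
    phi <- runif(1, 0, 2 * pi)
    d <- runif(1, params$core_clearance[1L], params$core_clearance[2L])
    r <- boundary_radius(core, phi) + d + extent
    c(core$cx + r * cos(phi), core$cy + r * sin(phi), phi)
  }

  for (i in seq_len(params$n_single_cells)) {
    place(function() {
      r <- runif(1, params$cell_radius[1L], params$cell_radius[2L])
      cc <- sample_centre(r)
      render_disk(h, w, cc[1L], cc[2L], r)
    }, params$cell_intensity)
  }
  for (i in seq_len(params$n_strands)) {
    place(function() {
      len <- runif(1, params$strand_length[1L], params$strand_length[2L])
      hw <- runif(1, params$strand_width[1L], params$strand_width[2L]) / 2
      cc <- sample_centre(len / 2)
      ang <- cc[3L] + runif(1, -pi / 9, pi / 9)  # roughly radial
      dx <- cos(ang) * len / 2; dy <- sin(ang) * len / 2
      render_capsule(h, w, cc[1L] - dx, cc[2L] - dy, cc[1L] + dx, cc[2L] + dy, hw)
    }, params$strand_intensity)
  }
  for (i in seq_len(params$n_touching_pairs)) {
    # one connected blob with two distance-transform peaks
    r <- params$touch_radius; s <- params$touch_sep
    place(function() {
      cc <- sample_centre(r + s / 2)
      ang <- runif(1, 0, pi)
      dx <- cos(ang) * s / 2; dy <- sin(ang) * s / 2
      render_disk(h, w, cc[1L] - dx, cc[2L] - dy, r) |
        render_disk(h, w, cc[1L] + dx, cc[2L] + dy, r)
    }, params$cell_intensity)
  }
  for (i in seq_len(params$n_straddling)) {
    # blob centred on the core edge; only its outside part is a particle
    r <- mean(params$cell_radius) * 2
    placed <- FALSE
    for (try in 1:200) {
      phi <- runif(1, 0, 2 * pi)
      rb <- boundary_radius(core, phi)
      cx <- core$cx + rb * cos(phi); cy <- core$cy + rb * sin(phi)
      fp <- render_disk(h, w, cx, cy, r)
      outside <- fp & !core_mask
      if (!any(outside) || any(fp & occupied_particles)) next
      n_lab <- n_lab + 1L
      labels[outside] <- n_lab
      objects[[length(objects) + 1L]] <- list(fp = fp,
                                              intensity = params$cell_intensity)
      grown <- matrix(EBImage::dilate(fp, brush) > 0, h, w)
      occupied <- occupied | grown
      occupied_particles <- occupied_particles | grown
      placed <- TRUE
      break
    }
    if (!placed)
      stop("straddling-blob placement failed after 200 attempts")
  }

  labels <- compact_labels(labels)

  gfp_mask <- core_mask
  for (obj in objects) gfp_mask <- gfp_mask | obj$fp

  # slice surface line achieving the target submergence on the rendered mask
  rows <- which(gfp_mask, arr.ind = TRUE)[, 1L]
  counts <- tabulate(rows, nbins = h)
  below <- rev(cumsum(rev(counts)))          # below[L] = #pixels with y >= L
  frac <- below / length(rows)
  surface_line <- which.min(abs(frac - params$submergence))
  truth_pct <- 100 * frac[surface_line]

  # tumour channel
  gfp <- matrix(params$background, h, w)
  gfp[core_mask] <- params$core_intensity
  for (obj in objects) gfp[obj$fp] <- obj$intensity
  if (params$noise_sd > 0)
    gfp <- gfp + rnorm(h * w, 0, params$noise_sd)
  gfp <- round(pmin(pmax(gfp, 0), 65535))

  # tissue channel: textured below the surface line, dark above it
  tissue <- matrix(2, h, w)
  if (surface_line <= h) {
    sub_rows <- surface_line:h
    tissue[sub_rows, ] <- params$tissue_level +
      rnorm(length(sub_rows) * w, 0, 8)
  }
  tissue <- round(pmin(pmax(tissue, 0), 65535))

  stack <- channel_stack(
    calibrated_image(gfp, params$pixel_size, "GFP"),
    calibrated_image(tissue, params$pixel_size, "GFAP")
  )
  truth_table <- measure_particles(labels, core, params$pixel_size,
                                   distance_mode = "centroid")
  structure(list(stack = stack, truth_core = core, truth_labels = labels,
                 truth_table = truth_table, truth_pct_within = truth_pct,
                 surface_line = surface_line, params = params),
            class = "synth_scene")
}

#' @export
print.synth_scene <- function(x, ...) {
  cat(sprintf(
    "synth_scene %dx%d px, %d particle(s), %.1f%% within slice (seed %d)\n",
    x$params$height, x$params$width, max(x$truth_labels),
    x$truth_pct_within, x$params$seed))
  invisible(x)
}

#' Write the standard validation fixture battery
#'
#' Renders a fixed set of scenes exercising every pipeline stage — clean,
#' noisy, touching particles, a blob straddling the core rim, and three
#' submergence levels — and writes each as `<scene>/image.tif` (with its
#' calibration sidecar), `<scene>/truth_particles.csv` and
#' `<scene>/truth_meta.json` (core ellipse, surface line, achieved
#' submergence, seed).
#'
#' @param out_dir Output directory (created if needed).
#' @param base_seed Integer; scene `i` uses `base_seed + i`.
#' @return Named character vector of scene directories, invisibly.
#' @export
render_fixture_suite <- function(out_dir, base_seed = 100L) {
  specs <- list(
    clean      = scene_params(noise_sd = 0, seed = base_seed + 1L),
    noisy      = scene_params(noise_sd = 30, seed = base_seed + 2L),
    touching   = scene_params(n_single_cells = 4, n_strands = 0,
                              n_touching_pairs = 2, noise_sd = 0,
                              seed = base_seed + 3L),
    straddle   = scene_params(n_single_cells = 6, n_strands = 2,
                              n_straddling = 1, noise_sd = 0,
                              seed = base_seed + 4L),
    submerge25 = scene_params(n_single_cells = 0, n_strands = 0,
                              submergence = 0.25, noise_sd = 0,
                              seed = base_seed + 5L),
    submerge50 = scene_params(n_single_cells = 0, n_strands = 0,
                              submergence = 0.5, noise_sd = 0,
                              seed = base_seed + 6L),
    submerge100 = scene_params(n_single_cells = 0, n_strands = 0,
                               submergence = 1, noise_sd = 0,
                               seed = base_seed + 7L)
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create fixture directory: ", out_dir)
  dirs <- character(0L)
  for (nm in names(specs)) {
    sc <- generate_scene(specs[[nm]])
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    write_stack(sc$stack, file.path(d, "image.tif"))
    write.csv(sc$truth_table, file.path(d, "truth_particles.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(core = unclass(sc$truth_core),
           surface_line = sc$surface_line,
           pct_within = sc$truth_pct_within,
           n_particles = nrow(sc$truth_table),
           pixel_size = sc$params$pixel_size,
           seed = sc$params$seed),
      file.path(d, "truth_meta.json"), auto_unbox = TRUE, digits = NA)
    dirs[nm] <- d
  }
  invisible(dirs)
}
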