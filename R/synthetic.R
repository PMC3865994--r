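#' Specification of a synthetic bright-field scene
#'
#' Describes a field of rod-shaped (spherocylindrical) cells as imaged in
#' transmitted illumination: the membrane appears as a dark ring straddling
#' the cell boundary and the interior is brighter than the background. An
#' optional bilinear focus plane inverts the cell-attributable contrast on
#' one side of its zero line, emulating a specimen plane tilted against the
#' focal plane. A fraction of cells carries a Gaussian nucleus blob in the
#' fluorescence channel.
#'
#' Intensities are on an 8-bit-like scale (dynamic range 255). The ground
#' truth instance mask of a cell extends to the membrane-ring centerline
#' (the ring is drawn half inside, half outside the cell footprint).
#'
#' @param shape image height and width in px.
#' @param n_cells number of cells to place.
#' @param length_range total cell length range (px, including end caps).
#' @param width cell width across the membrane centerline (px).
#' @param membrane_width,membrane_depth ring width (px) and intensity drop
#'   below background.
#' @param interior_lift interior intensity above background.
#' @param background_level mean background intensity mu_B.
#' @param noise_sd additive Gaussian noise sigma.
#' @param focus_plane `NULL` or coefficients `c(a, b, c)` of
#'   `z(x, y) = a + b*x + c*y`; deviations are negated where `z < 0`.
#' @param nucleus_radius Gaussian blob sigma and truth-mask radius (px).
#' @param nucleus_fraction fraction of cells bearing a fluorescent nucleus.
#' @param min_gap minimum clearance between cell outer edges (px).
#' @param edge_cells number of cells deliberately placed crossing the frame
#'   border (truncated cells for validation training / border handling).
#' @param septating_pairs number of abutting rod pairs sharing a membrane
#'   wall (cells in septation); counted within `n_cells`.
#' @param seed RNG seed; the scene is a pure function of the spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(512L, 512L),
                       n_cells = 28L,
                       length_range = c(25, 45),
                       width = 11,
                       membrane_width = 3,
                       membrane_depth = 30,
                       interior_lift = 20,
                       background_level = 128,
                       noise_sd = 5,
                       focus_plane = NULL,
                       nucleus_radius = 3,
                       nucleus_fraction = 0.8,
                       min_gap = 4,
                       edge_cells = 0L,
                       septating_pairs = 0L,
                       seed = 1L) {
  if (any(length_range <= width))
    ps_error("cell length must exceed width", "pombeseg_validation_error")
  structure(as.list(environment()), class = "scene_spec")
}

#' Named fixture presets
#'
#' `"wildtype"`: short rods; `"cdc"`: elongated rods (cell-division-cycle
#' arrest phenotype); `"mixed"`: broad size range; `"septating"`: abutting
#' rod pairs sharing a septum wall; `"wildtype_gradient"`: wildtype plus a
#' focus plane whose z = 0 line crosses the frame, inverting contrast over
#' roughly a fifth of the image.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param shape image shape; cell counts scale with area.
#' @return a `scene_spec`.
#' @export
scene_preset <- function(name = c("wildtype", "cdc", "mixed", "septating",
                                  "wildtype_gradient"),
                         seed = 1L, shape = c(512L, 512L)) {
  name <- match.arg(name)
  sc <- prod(shape) / (512^2)
  n <- function(k) max(4L, as.integer(round(k * sc)))
  switch(name,
    wildtype = scene_spec(shape = shape, n_cells = n(28), edge_cells = 3L,
                          seed = seed),
    cdc = scene_spec(shape = shape, n_cells = n(10),
                     length_range = c(60, 110), width = 12, edge_cells = 2L,
                     seed = seed),
    mixed = scene_spec(shape = shape, n_cells = n(22),
                       length_range = c(22, 80), edge_cells = 2L, seed = seed),
    septating = scene_spec(shape = shape, n_cells = n(24),
                           length_range = c(22, 30), septating_pairs = n(8),
                           seed = seed),
    wildtype_gradient = scene_spec(shape = shape, n_cells = n(28),
                                   edge_cells = 3L,
                                   focus_plane = c(-0.22 * shape[2], 1, 0),
                                   seed = seed)
  )
}

# distance from grid points to a segment p0-p1 (all 0-based coords)
seg_dist_grid <- function(xs, ys, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  l2 <- vx^2 + vy^2
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  if (l2 == 0) return(sqrt((X - p0[1])^2 + (Y - p0[2])^2))
  t <- ((X - p0[1]) * vx + (Y - p0[2]) * vy) / l2
  t <- pmin(pmax(t, 0), 1)
  sqrt((X - (p0[1] + t * vx))^2 + (Y - (p0[2] + t * vy))^2)
}

seg_seg_dist <- function(a0, a1, b0, b1) {
  # minimum distance between two segments (sampled — adequate for packing)
  ts <- seq(0, 1, length.out = 17)
  pa <- cbind(a0[1] + ts * (a1[1] - a0[1]), a0[2] + ts * (a1[2] - a0[2]))
  pb <- cbind(b0[1] + ts * (b1[1] - b0[1]), b0[2] + ts * (b1[2] - b0[2]))
  min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2))
}

downsample_block <- function(m, f) {
  h <- nrow(m) / f; w <- ncol(m) / f
  m1 <- matrix(colMeans(matrix(m, nrow = f)), nrow = h)
  t(matrix(colMeans(matrix(t(m1), nrow = f)), nrow = w))
}

#' Generate a synthetic scene with ground truth
#'
#' Rasterizes the cells of a [scene_spec()] with x4 supersampled
#' (anti-aliased) edges, applies the focus plane if present, adds noise, and
#' returns the channels together with exact ground truth.
#'
#' @param spec a `scene_spec`.
#' @return a `synthetic_scene`: list with `field` (a [field_images()]),
#'   `truth` (instance label mask to the ring centerline, class map coded
#'   with [CLASS_BACKGROUND] / [CLASS_INTERIOR] / [CLASS_MEMBRANE], nucleus
#'   mask and centers, per-cell geometry table), and the clean deviation /
#'   noise layers used to compose the image.
#' @export
generate_scene <- function(spec) {
  with_local_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  h <- spec$shape[1]; w <- spec$shape[2]
  Rr <- spec$width / 2
  wm <- spec$membrane_width
  outer_r <- Rr + wm / 2
  cells <- place_cells(spec, h, w, Rr, outer_r)
  nc <- nrow(cells)

  ss <- 4L
  mem_ss <- matrix(FALSE, h * ss, w * ss)
  int_ss <- matrix(FALSE, h * ss, w * ss)
  mem_px <- matrix(FALSE, h, w)
  int_px <- matrix(FALSE, h, w)
  best_d <- matrix(Inf, h, w)
  best_id <- matrix(0L, h, w)

  for (i in seq_len(nc)) {
    p0 <- c(cells$x0[i], cells$y0[i]); p1 <- c(cells$x1[i], cells$y1[i])
    pad <- outer_r + 1.5
    xlo <- max(0, floor(min(p0[1], p1[1]) - pad))
    xhi <- min(w - 1, ceiling(max(p0[1], p1[1]) + pad))
    ylo <- max(0, floor(min(p0[2], p1[2]) - pad))
    yhi <- min(h - 1, ceiling(max(p0[2], p1[2]) + pad))
    if (xhi < xlo || yhi < ylo) next
    # supersampled deviations
    Jlo <- xlo * ss + 1L; Jhi <- (xhi + 1L) * ss
    Ilo <- ylo * ss + 1L; Ihi <- (yhi + 1L) * ss
    xs_ss <- ((Jlo:Jhi) - 0.5) / ss - 0.5
    ys_ss <- ((Ilo:Ihi) - 0.5) / ss - 0.5
    d_ss <- seg_dist_grid(xs_ss, ys_ss, p0, p1)
    mem_c <- d_ss >= Rr - wm / 2 & d_ss <= Rr + wm / 2
    int_c <- d_ss < Rr - wm / 2
    mem_ss[Ilo:Ihi, Jlo:Jhi] <- mem_ss[Ilo:Ihi, Jlo:Jhi] | mem_c
    int_ss[Ilo:Ihi, Jlo:Jhi] <- int_ss[Ilo:Ihi, Jlo:Jhi] | int_c
    # pixel-center truth
    xs <- xlo:xhi; ys <- ylo:yhi
    d <- seg_dist_grid(xs, ys, p0, p1)
    ri <- (ylo:yhi) + 1L; ci <- (xlo:xhi) + 1L
    mem_px[ri, ci] <- mem_px[ri, ci] | (abs(d - Rr) <= wm / 2)
    int_px[ri, ci] <- int_px[ri, ci] | (d < Rr - wm / 2)
    upd <- d < best_d[ri, ci]
    bd <- best_d[ri, ci]; bi <- best_id[ri, ci]
    bd[upd] <- d[upd]; bi[upd] <- i
    best_d[ri, ci] <- bd; best_id[ri, ci] <- bi
  }

  dev_ss <- -spec$membrane_depth * mem_ss +
    spec$interior_lift * (int_ss & !mem_ss)
  clean_dev <- downsample_block(dev_ss, ss)

  instance <- matrix(0L, h, w)
  inside <- is.finite(best_d) & best_d <= Rr
  instance[inside] <- best_id[inside]
  class_map <- matrix(CLASS_BACKGROUND, h, w)
  class_map[int_px & !mem_px] <- CLASS_INTERIOR
  class_map[mem_px] <- CLASS_MEMBRANE

  # nuclei
  nuc_mask <- matrix(FALSE, h, w)
  fl <- matrix(5, h, w)
  centers <- cells[cells$has_nucleus, c("cx", "cy"), drop = FALSE]
  for (i in which(cells$has_nucleus)) {
    ctr <- c(cells$cx[i], cells$cy[i])
    rad <- ceiling(3 * spec$nucleus_radius)
    xlo <- max(0, floor(ctr[1] - rad)); xhi <- min(w - 1, ceiling(ctr[1] + rad))
    ylo <- max(0, floor(ctr[2] - rad)); yhi <- min(h - 1, ceiling(ctr[2] + rad))
    if (xhi < xlo || yhi < ylo) next
    d <- seg_dist_grid(xlo:xhi, ylo:yhi, ctr, ctr)
    ri <- (ylo:yhi) + 1L; ci <- (xlo:xhi) + 1L
    fl[ri, ci] <- fl[ri, ci] + 100 * exp(-d^2 / (2 * spec$nucleus_radius^2))
    nuc_mask[ri, ci] <- nuc_mask[ri, ci] | (d <= spec$nucleus_radius)
  }
  fl <- fl + matrix(rnorm(h * w, 0, 2), h, w)

  noise <- matrix(rnorm(h * w, 0, spec$noise_sd), h, w)

  scene <- structure(list(
    spec = spec,
    clean_dev = clean_dev,
    noise = noise,
    truth = list(instance = instance, class_map = class_map,
                 nucleus_mask = nuc_mask,
                 nucleus_centers = as.matrix(centers),
                 cells = cells, plane = NULL),
    fluor = fl
  ), class = "synthetic_scene")
  if (!is.null(spec$focus_plane))
    scene <- apply_focus_plane(scene, spec$focus_plane)
  compose_scene(scene)
}

# rebuild the field_images from the deviation + noise layers
compose_scene <- function(scene) {
  spec <- scene$spec
  trans <- spec$background_level + scene$clean_dev + scene$noise
  scene$field <- field_images(trans, list(scene$fluor), dynamic_range = 255)
  scene
}

#' Invert cell contrast where a focus plane is negative
#'
#' Negates the cell-attributable intensity deviations from the background
#' mean wherever `z(x, y) = a + b*x + c*y < 0`, which is exactly the
#' distortion the adaptive focus correction must undo. Applying the same
#' plane twice restores the original scene (double negation).
#'
#' @param scene a `synthetic_scene`.
#' @param plane coefficients `c(a, b, c)`.
#' @return the modified scene (field recomposed, plane recorded in truth).
#' @export
apply_focus_plane <- function(scene, plane) {
  if (!all(is.finite(plane)) || length(plane) != 3L)
    ps_error("plane must be 3 finite coefficients", "pombeseg_validation_error")
  h <- nrow(scene$clean_dev); w <- ncol(scene$clean_dev)
  z <- plane_values(plane, h, w)
  scene$clean_dev[z < 0] <- -scene$clean_dev[z < 0]
  scene$truth$plane <- plane
  compose_scene(scene)
}

plane_values <- function(plane, height, width) {
  x <- matrix(0:(width - 1), height, width, byrow = TRUE)
  y <- matrix(0:(height - 1), height, width)
  plane[1] + plane[2] * x + plane[3] * y
}

place_cells <- function(spec, h, w, Rr, outer_r) {
  n <- spec$n_cells
  placed <- list()
  add_cell <- function(cx, cy, th, len, pair = NA_integer_) {
    hl <- (len - 2 * Rr) / 2
    x0 <- cx - hl * cos(th); y0 <- cy - hl * sin(th)
    x1 <- cx + hl * cos(th); y1 <- cy + hl * sin(th)
    data.frame(cx = cx, cy = cy, theta = th, length = len, hl = hl, R = Rr,
               x0 = x0, y0 = y0, x1 = x1, y1 = y1, pair = pair)
  }
  fits <- function(cand, ignore_pair = NA) {
    for (p in placed) {
      if (!is.na(ignore_pair) && !is.na(p$pair) && p$pair == ignore_pair) next
      d <- seg_seg_dist(c(cand$x0, cand$y0), c(cand$x1, cand$y1),
                        c(p$x0, p$y0), c(p$x1, p$y1))
      if (d < 2 * outer_r + spec$min_gap) return(FALSE)
    }
    TRUE
  }
  rand_len <- function() runif(1, spec$length_range[1], spec$length_range[2])

  n_sept <- 2L * spec$septating_pairs
  n_edge <- min(spec$edge_cells, n - n_sept)
  n_free <- n - n_sept - n_edge
  attempts <- 0L; max_attempts <- 400L * n

  # septating pairs: two collinear capsules abutting at a shared wall
  pair_id <- 0L
  while (pair_id < spec$septating_pairs) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      ps_error(sprintf("cell placement infeasible: placed %d of %d",
                       length(placed), n), "pombeseg_placement_error")
    len <- rand_len(); th <- runif(1, 0, pi)
    hl <- (len - 2 * Rr) / 2
    off <- hl + Rr - spec$membrane_width / 2
    half_extent <- 2 * off + hl + outer_r
    mx <- runif(1, half_extent, w - 1 - half_extent)
    my <- runif(1, half_extent, h - 1 - half_extent)
    c1 <- add_cell(mx - off * cos(th), my - off * sin(th), th, len,
                   pair = pair_id + 1L)
    c2 <- add_cell(mx + off * cos(th), my + off * sin(th), th, len,
                   pair = pair_id + 1L)
    if (fits(c1, ignore_pair = pair_id + 1L) &&
        fits(c2, ignore_pair = pair_id + 1L)) {
      placed <- c(placed, list(c1, c2))
      pair_id <- pair_id + 1L
    }
  }

  # border-crossing cells: center pulled outside so the rod is truncated
  placed_edge <- 0L
  while (placed_edge < n_edge) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      ps_error(sprintf("cell placement infeasible: placed %d of %d",
                       length(placed), n), "pombeseg_placement_error")
    len <- rand_len(); side <- sample(4L, 1L)
    th <- runif(1, 0, pi)
    over <- runif(1, 0.2, 0.45) * len  # this much of the rod lies outside
    pos <- switch(side,
      c(runif(1, 40, w - 41), -over + len / 2),        # top, axis vertical
      c(runif(1, 40, w - 41), h - 1 + over - len / 2), # bottom
      c(-over + len / 2, runif(1, 40, h - 41)),        # left, axis horizontal
      c(w - 1 + over - len / 2, runif(1, 40, h - 41))) # right
    thv <- if (side <= 2L) pi / 2 else 0
    cand <- add_cell(pos[1], pos[2], thv, len)
    if (fits(cand)) { placed <- c(placed, list(cand)); placed_edge <- placed_edge + 1L }
  }

  # free interior cells
  placed_free <- 0L
  while (placed_free < n_free) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      ps_error(sprintf("cell placement infeasible: placed %d of %d",
                       length(placed), n), "pombeseg_placement_error")
    len <- rand_len(); th <- runif(1, 0, pi)
    hl <- (len - 2 * Rr) / 2
    margin <- hl + outer_r + 2
    cx <- runif(1, margin, w - 1 - margin)
    cy <- runif(1, margin, h - 1 - margin)
    cand <- add_cell(cx, cy, th, len)
    if (fits(cand)) { placed <- c(placed, list(cand)); placed_free <- placed_free + 1L }
  }

  cells <- do.call(rbind, placed)
  cells$id <- seq_len(nrow(cells))
  cells$border <- cells$x0 < outer_r | cells$x1 < outer_r |
    cells$y0 < outer_r | cells$y1 < outer_r |
    cells$x0 > w - 1 - outer_r | cells$x1 > w - 1 - outer_r |
    cells$y0 > h - 1 - outer_r | cells$y1 > h - 1 - outer_r
  cells$has_nucleus <- runif(nrow(cells)) < spec$nucleus_fraction
  cells
}
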