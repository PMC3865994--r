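test_that("constant edge maps give an identically zero field", {
  f <- matrix(0.4, 16, 16)
  gvf <- compute_gvf(f, n_iter = 10)
  expect_true(all(gvf$u == 0))
  expect_true(all(gvf$v == 0))
})

test_that("the field is invariant to adding a constant to the edge map", {
  f <- circle_edge_map(32, 10)
  g1 <- compute_gvf(f, n_iter = 30)
  g2 <- compute_gvf(f + 5, n_iter = 30)
  expect_equal(g1$u, g2$u, tolerance = 1e-12)
  expect_equal(g1$v, g2$v, tolerance = 1e-12)
})

test_that("with vanishing regularization the field approaches the edge gradient", {
  f <- circle_edge_map(32, 10)
  gvf <- compute_gvf(f, mu = 1e-4, n_iter = 400, dt = 0.9 * 0.25 / 1e-4 * 1e-3)
  g <- gvf$fx^2 + gvf$fy^2
  strong <- g > 0.5 * max(g)
  expect_equal(gvf$u[strong], gvf$fx[strong], tolerance = 1e-3)
  expect_equal(gvf$v[strong], gvf$fy[strong], tolerance = 1e-3)
})

test_that("the stability bound on the time step is enforced", {
  f <- circle_edge_map(32, 10)
  expect_error(compute_gvf(f, mu = 0.8, n_iter = 5, dt = 0.5),
               class = "pombeseg_validation_error")
})

test_that("solver matches the independent energy-descent oracle on a 32x32 ridge", {
  f <- circle_edge_map(32, 11, sigma = 1.5)
  n_iter <- 400
  gvf <- compute_gvf(f, mu = 0.8, n_iter = n_iter)
  oracle <- gvf_descent_oracle(f, mu = 0.8, n_iter = n_iter, dt = gvf$dt)
  rms <- sqrt(mean((gvf$u - oracle$u)^2 + (gvf$v - oracle$v)^2))
  expect_lte(rms, 1e-6)
})

test_that("the discretized GVF energy is non-increasing across iterations", {
  f <- circle_edge_map(32, 11)
  e_prev <- Inf
  for (k in c(1, 2, 5, 10, 20, 40, 80, 160)) {
    gvf <- compute_gvf(f, mu = 0.8, n_iter = k)
    e <- gvf_energy(gvf$u, gvf$v, gvf$fx, gvf$fy, 0.8)
    expect_lte(e, e_prev + 1e-12)
    e_prev <- e
  }
})

test_that("internal energy behaves like tension plus rigidity", {
  ctr <- 0
  for (r in c(10, 5, 2)) {
    e <- internal_energy(circle_contour(r, 24, 0))
    if (ctr > 0) expect_lt(e, e_last)
    e_last <- e; ctr <- ctr + 1
  }
  # collinear equally spaced vertices contribute zero bending: growing the
  # straight sides of a rectangle (same spacing, same corners) leaves the
  # rigidity-only energy unchanged
  rect_pts <- function(w) {
    top <- cbind(x = 0:w, y = 0)
    right <- cbind(x = w, y = 1:4)
    bottom <- cbind(x = w:0, y = 4)
    left <- cbind(x = 0, y = 3:1)
    rbind(top, right, bottom, left)
  }
  e10 <- internal_energy(rect_pts(10), alpha = 0, beta = 1)
  e25 <- internal_energy(rect_pts(25), alpha = 0, beta = 1)
  expect_equal(e10, e25, tolerance = 1e-12)
  expect_equal(internal_energy(circle_contour(7, 20, 0), 0, 0), 0)
})

test_that("a snake with zero external force shrinks monotonically", {
  field <- structure(list(u = matrix(0, 64, 64), v = matrix(0, 64, 64)),
                     class = "gvf_field")
  v <- circle_contour(20, 40, 31.5)
  areas <- polygon_area(v)
  for (k in 1:5) {
    v <- evolve_snake(v, field, n_iter = 20, tol = 0)
    areas <- c(areas, polygon_area(as.matrix(v[, 1:2])))
  }
  expect_true(all(diff(areas) < 0))
})

test_that("snake converges onto a circular ridge within a pixel", {
  f <- circle_edge_map(64, 20)
  gvf <- compute_gvf(f, n_iter = 80)
  fin <- evolve_snake(circle_contour(14, 40, 31.5), gvf, n_iter = 200)
  r <- sqrt((fin[, 1] - 31.5)^2 + (fin[, 2] - 31.5)^2)
  expect_lte(mean(abs(r - 20)), 1)
  expect_false(attr(fin, "degenerate"))
})

test_that("a snake already on the ridge stays put", {
  f <- circle_edge_map(64, 20)
  gvf <- compute_gvf(f, n_iter = 80)
  start <- circle_contour(20, 40, 31.5)
  fin <- evolve_snake(start, gvf, n_iter = 400)
  r <- sqrt((fin[, 1] - 31.5)^2 + (fin[, 2] - 31.5)^2)
  expect_lte(max(abs(r - 20)), 0.5)
})

test_that("final contours never leave the image bounds", {
  f <- matrix(0, 32, 32); f[16, 16] <- 1
  f <- pombeseg:::gaussian_blur(f, 1); f <- f / max(f)
  gvf <- compute_gvf(f, n_iter = 40)
  v <- circle_contour(20, 40, 16)   # partly out of bounds on purpose
  fin <- evolve_snake(v, gvf, n_iter = 50)
  expect_true(all(fin[, 1] >= 0 & fin[, 1] <= 31))
  expect_true(all(fin[, 2] >= 0 & fin[, 2] <= 31))
})

test_that("segment_cells produces one contour per interior component", {
  scene <- small_scene()
  cfg <- pipeline_config()
  regions <- detect_regions(scene$field, cfg)
  fc <- correct_focus(regions, cfg, delta = 0.15 * 255)
  cmap <- resolve_ambiguous(smooth_classes(
    classify_pixels(fc$image, regions$background, fc$mu_N, fc$mu_B),
    cfg$se_radius))
  seg <- segment_cells(cmap, cfg)
  ncomp <- length(initial_contours(cmap, cfg$min_cell_area))
  expect_length(seg$contours, ncomp)
  expect_equal(sort(unique(as.integer(seg$label_mask))),
               0:length(seg$contours))
  # empty interior set -> empty result
  L <- matrix(CLASS_BACKGROUND, 32, 32)
  seg0 <- segment_cells(pombeseg:::new_pixel_class_map(L), cfg)
  expect_length(seg0$contours, 0)
  expect_true(all(seg0$label_mask == 0L))
})
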