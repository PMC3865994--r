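test_that("noiseless plane samples are recovered to machine precision", {
  set.seed(5)
  x <- runif(20, 0, 500); y <- runif(20, 0, 500)
  z <- 2 + 0.1 * x - 0.05 * y
  fit <- fit_focus_plane(data.frame(x = x, y = y, z = z))
  expect_equal(unname(fit$coeffs), c(2, 0.1, -0.05), tolerance = 1e-10)
})

test_that("noisy plane fit matches the normal-equations oracle and recovers truth", {
  set.seed(11)
  n <- 100
  x <- runif(n, 0, 500); y <- runif(n, 0, 500)
  z <- 2 + 0.1 * x - 0.05 * y + rnorm(n, 0, 0.5)
  fit <- fit_focus_plane(data.frame(x = x, y = y, z = z))
  # closed-form least squares via the normal equations
  X <- cbind(1, x, y)
  beta <- solve(t(X) %*% X, t(X) %*% z)
  expect_equal(unname(fit$coeffs), as.numeric(beta), tolerance = 1e-8)
  # recovered within 3 standard errors of the truth
  expect_true(all(abs(fit$coeffs - c(2, 0.1, -0.05)) <= 3 * fit$se))
})

test_that("rank-deficient designs raise a fit error", {
  s <- data.frame(x = c(0, 1, 2), y = c(0, 2, 4), z = c(1, 2, 3))
  expect_error(fit_focus_plane(s), class = "pombeseg_fit_error")
  expect_error(fit_focus_plane(s[1:2, ]), class = "pombeseg_fit_error")
})

test_that("complementation reflects about mu_B, fixes mu_B, and is an involution", {
  img <- matrix(as.double(60:95), 6, 6)
  img[2, 2] <- 80; img[5, 5] <- 100
  plane <- c(-2.5, 1, 0)  # z < 0 for x < 2.5 (first three columns)
  out <- complement_negative_region(img, plane, mu_B = 100)
  expect_equal(out[2, 2], 120)            # j = 2*100 - 80
  expect_equal(out[5, 5], 100)            # x = 4 >= 2.5: unchanged
  img2 <- img; img2[3, 1] <- 100
  out2 <- complement_negative_region(img2, plane, mu_B = 100)
  expect_equal(out2[3, 1], 100)           # mu_B is a fixed point
  twice <- complement_negative_region(out, plane, mu_B = 100)
  expect_identical(twice, img)            # involution, bit-identical
})

test_that("global contrast adjustment hits the target and flips inverted contrast", {
  img <- matrix(c(5, 0, 10, 3), 2, 2)
  out <- global_contrast_adjust(img, mu_N = 10, mu_B = 0, delta = 20)
  expect_equal(out[1, 1], 10)             # i = 5 -> 10
  # already at target: identity
  expect_equal(global_contrast_adjust(img, mu_N = 20, mu_B = 0, delta = 20), img)
  # inverted contrast: mu_N < mu_B, sign flip absorbed
  expect_equal(global_contrast_adjust(matrix(80, 1, 1), mu_N = 80, mu_B = 100,
                                      delta = 40)[1, 1], 140)
  expect_error(global_contrast_adjust(img, mu_N = 5, mu_B = 5, delta = 20),
               class = "pombeseg_validation_error")
})

test_that("contrast adjustment is idempotent once the target is reached", {
  set.seed(3)
  img <- matrix(rnorm(100, 50, 10), 10, 10)
  nm <- matrix(FALSE, 10, 10); nm[1:3, ] <- TRUE
  bm <- matrix(FALSE, 10, 10); bm[8:10, ] <- TRUE
  mu <- region_means(img, nm, bm)
  out1 <- global_contrast_adjust(img, mu[["mu_N"]], mu[["mu_B"]], 25)
  mu1 <- region_means(out1, nm, bm)
  expect_equal(mu1[["mu_N"]] - mu1[["mu_B"]], 25, tolerance = 1e-9)
  out2 <- global_contrast_adjust(out1, mu1[["mu_N"]], mu1[["mu_B"]], 25)
  expect_equal(out2, out1, tolerance = 1e-9)
})

test_that("focus gradient detection needs a sign change and explained variance", {
  dims <- c(100, 100)
  s_pos <- data.frame(x = c(10, 50, 90, 30), y = c(10, 80, 20, 60),
                      z = c(5, 6, 7, 5.5))
  expect_false(detect_focus_gradient(s_pos, dims))      # all z > 0
  set.seed(8)
  x <- runif(30, 0, 99); y <- runif(30, 0, 99)
  z <- -20 + 0.45 * x + rnorm(30, 0, 1)
  expect_true(detect_focus_gradient(data.frame(x = x, y = y, z = z), dims))
  z_noise <- rnorm(30, 0, 1) + c(-0.5, 0.5)             # sign change, no structure
  expect_false(detect_focus_gradient(data.frame(x = x, y = y, z = z_noise), dims))
  s_flat <- data.frame(x = x[1:5], y = y[1:5], z = rep(2, 5))
  expect_false(detect_focus_gradient(s_flat, dims))     # b = c = 0
})

test_that("full correction restores contrast polarity on both halves of an inverted scene", {
  scene <- test_scene("wildtype_gradient", 7)
  cfg <- pipeline_config()
  regions <- detect_regions(scene$field, cfg)
  fc <- correct_focus(regions, cfg, delta = 0.15 * 255)
  expect_true(fc$complemented)
  z <- pombeseg:::plane_values(scene$truth$plane, 512, 512)
  interior <- scene$truth$class_map == CLASS_INTERIOR
  membrane <- scene$truth$class_map == CLASS_MEMBRANE
  for (side in list(z < 0, z >= 0)) {
    expect_gt(mean(fc$image[interior & side]), fc$mu_B)
    expect_lt(mean(fc$image[membrane & side]), fc$mu_B)
  }
})
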