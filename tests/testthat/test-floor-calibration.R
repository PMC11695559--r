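test_that("identity correspondences give the identity homography", {
  pairs <- data.frame(img_x = c(0, 1, 1, 0), img_y = c(0, 0, 1, 1),
                      floor_x = c(0, 1, 1, 0), floor_y = c(0, 0, 1, 1))
  h <- estimate_homography(pairs)
  expect_equal(unclass(h), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("estimation recovers the generating homography from noiseless scenes", {
  for (seed in 1:5) {
    h_true <- proj_homography()
    sc <- synth_calibration_scene(h_true, n_points = 5 + seed %% 3,
                                  noise_sd = 0, rng_seed = seed)
    h_est <- estimate_homography(sc)
    expect_lt(max(abs(unclass(h_est) - unclass(h_true))), 1e-6)
  }
})

test_that("too few or degenerate correspondences raise errors", {
  pairs <- data.frame(img_x = 1:3, img_y = c(1, 2, 3),
                      floor_x = 1:3, floor_y = c(1, 2, 3))
  expect_error(estimate_homography(pairs), "insufficient")
  collinear <- data.frame(img_x = 1:5, img_y = 1:5,
                          floor_x = 1:5, floor_y = 1:5)
  expect_error(estimate_homography(collinear), "degenerate")
  expect_error(synth_calibration_scene(diag(3), n_points = 3), "at least 4")
})

test_that("projection follows closed forms and round trips", {
  expect_equal(project_to_floor(diag(3), c(10, 20)), c(x = 10, y = 20))
  h2 <- diag(c(2, 2, 1))
  expect_equal(project_to_floor(h2, c(10, 20)), c(x = 20, y = 40))
  expect_equal(project_to_image(h2, c(20, 40)), c(x = 10, y = 20))
  h <- proj_homography()
  pts <- cbind(runif(20, 0, 1900), runif(20, 0, 1000))
  rt <- project_to_image(h, project_to_floor(h, pts))
  expect_lt(max(abs(rt - pts)), 1e-9)
})

test_that("projection of collinear floor points stays collinear", {
  h <- proj_homography()
  t <- seq(0, 1, length.out = 7)
  line <- cbind(10 + 250 * t, -60 + 100 * t)
  img <- project_to_image(h, line)
  # all points on the line through the first two
  d <- cbind(img[, 1] - img[1, 1], img[, 2] - img[1, 2])
  cross <- d[, 1] * d[2, 2] - d[, 2] * d[2, 1]
  expect_lt(max(abs(cross)), 1e-9)
})

test_that("estimation is invariant under similarity transforms of the inputs", {
  h_true <- proj_homography()
  sc <- synth_calibration_scene(h_true, n_points = 6, noise_sd = 0.5,
                                rng_seed = 3)
  h1 <- estimate_homography(sc)
  # apply a similarity to the image points; the composite estimate must
  # equal h1 composed with the inverse similarity
  s <- 3.7; a <- 0.4; tx <- 100; ty <- -50
  sim <- rbind(c(s * cos(a), -s * sin(a), tx),
               c(s * sin(a), s * cos(a), ty), c(0, 0, 1))
  p <- cbind(sc$img_x, sc$img_y, 1) %*% t(sim)
  sc2 <- sc
  sc2$img_x <- p[, 1] / p[, 3]
  sc2$img_y <- p[, 2] / p[, 3]
  h2 <- estimate_homography(sc2)
  comp <- unclass(h2) %*% sim
  comp <- comp / comp[3, 3]
  expect_equal(comp, unclass(h1), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("points mapped to infinity are reported", {
  h <- structure(matrix(c(1, 0, 0, 0, 1, 0, 0, -0.01, 1), 3, 3,
                        byrow = TRUE), class = "homography")
  expect_error(project_to_floor(h, c(5, 100)), "infinity")
})

test_that("correspondence files and homography JSON round trip", {
  sc <- synth_calibration_scene(proj_homography(), 6, 0, 1)
  f <- withr::local_tempfile(fileext = ".txt")
  write_correspondences(sc, f)
  back <- read_correspondences(f)
  expect_equal(back$floor_x, sc$floor_x, tolerance = 1e-6)
  h <- estimate_homography(sc)
  j <- withr::local_tempfile(fileext = ".json")
  write_homography_json(h, j)
  expect_equal(unclass(read_homography_json(j)), unclass(h),
               tolerance = 1e-12)
})
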