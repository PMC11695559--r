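test_that("floor-axis error follows its closed forms", {
  org <- image_point(0, 0)
  expect_equal(floor_axis_error(c(12, 5), c(10, 5), org, diag(3), "side"), 2)
  expect_equal(floor_axis_error(c(10, 5), c(10, 5), org, diag(3), "side"), 0)
  h2 <- diag(c(2, 2, 1))
  expect_equal(floor_axis_error(c(12, 5), c(10, 5), org, h2, "side"), 4)
  expect_equal(floor_axis_error(c(5, 12), c(5, 10), org, h2, "frontal"), 4)
})

test_that("side-view error ignores pure floor-y translations of the map", {
  h <- proj_homography()
  ty <- rbind(c(1, 0, 0), c(0, 1, 37.5), c(0, 0, 1)) # shift floor y only
  h2 <- structure(ty %*% unclass(h), class = "homography")
  e1 <- floor_axis_error(c(52, 88), c(47, 90), image_point(400, 300), h,
                         "side")
  e2 <- floor_axis_error(c(52, 88), c(47, 90), image_point(400, 300), h2,
                         "side")
  expect_equal(e1, e2, tolerance = 1e-9)
})

# Brute-force reference for the box-plot summary.
brute_summary <- function(v) {
  s <- sort(v)
  n <- length(s)
  qat <- function(p) {
    r <- p * (n - 1)
    lo <- floor(r) + 1
    hi <- ceiling(r) + 1
    s[lo] + (r - floor(r)) * (s[hi] - s[lo])
  }
  q1 <- qat(0.25); q2 <- qat(0.5); q3 <- qat(0.75)
  iqr <- q3 - q1
  nout <- sum(v > q3 + 1.5 * iqr | v < q1 - 1.5 * iqr)
  list(min = min(v), max = max(v), median = q2, q1 = q1, q3 = q3,
       iqr = iqr, outlier_fraction = nout / n)
}

test_that("summarize_errors matches the worked example and edge cases", {
  s <- summarize_errors(c(1, 2, 3, 4, 100))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$iqr, 2)
  expect_equal(s$outlier_fraction, 0.2)

  one <- summarize_errors(5)
  expect_equal(unlist(one[c("min", "max", "median", "q1", "q3")]),
               c(min = 5, max = 5, median = 5, q1 = 5, q3 = 5))
  expect_equal(one$iqr, 0)
  expect_equal(one$outlier_fraction, 0)

  const <- summarize_errors(rep(2.5, 9))
  expect_equal(const$iqr, 0)
  expect_equal(const$outlier_fraction, 0)

  expect_error(summarize_errors(numeric(0)), "empty")
})

test_that("summarize_errors agrees with brute force on small integer lists", {
  # exhaustive up to length 3, random lists for lengths 4..8
  lists <- list()
  for (v in 0:10) lists <- c(lists, list(v))
  for (a in 0:10) for (b in 0:10) lists <- c(lists, list(c(a, b)))
  set.seed(1)
  for (n in 3:8)
    for (i in 1:60) lists <- c(lists, list(sample(0:10, n, replace = TRUE)))
  for (v in lists) {
    got <- summarize_errors(v)
    ref <- brute_summary(v)
    for (f in names(ref))
      expect_equal(got[[f]], ref[[f]], tolerance = 1e-12,
                   label = paste(f, "of", paste(v, collapse = ",")))
  }
})

test_that("step parameters difference successive contacts", {
  sp <- step_parameters(rbind(c(0, 0), c(60, 10), c(120, 0)))
  expect_equal(sp$step_lengths, c(60, 60))
  expect_equal(sp$step_widths, c(10, 10))
  sp2 <- step_parameters(rbind(c(5, 5), c(5, 5)))
  expect_equal(sp2$step_lengths, 0)
  expect_error(step_parameters(rbind(c(1, 2))), "at least 2")
})

test_that("noiseless end-to-end recovery of planted step parameters", {
  h <- sim_homography()
  gp <- gait_scenario_params(120, heel_strike_frames = c(25, 50, 75, 100),
                             step_period = 25, step_length_world = 60,
                             step_width_world = 10)
  tr <- synth_gait_trajectories(gp, h, rng_seed = 2)
  d <- heel_to_heel_distance(keypoint_trajectory(tr$frames, "LHeel"),
                             keypoint_trajectory(tr$frames, "RHeel"))
  strikes <- detect_heel_strikes(d)
  expect_identical(strikes, c(25L, 50L, 75L, 100L))
  pts <- strike_floor_points(tr$frames, strikes, h)
  sp <- step_parameters(pts)
  expect_equal(sp$step_lengths, rep(60, 3), tolerance = 1e-6)
  expect_equal(sp$step_widths, rep(10, 3), tolerance = 1e-6)
  # ground-truth keypoints substituted for predictions give zero error
  f <- tr$frames[[26]]
  e <- floor_axis_error(f$keypoints["RHeel", c("x", "y")],
                        f$keypoints["RHeel", c("x", "y")],
                        image_point(0, 0), h, "side")
  expect_equal(e, 0)
})
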