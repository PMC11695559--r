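make_traj <- function(points, conf = rep(1, nrow(points)), frames = NULL) {
  structure(list(keypoint = "LHeel",
                 frames = frames %||% (seq_len(nrow(points)) - 1L),
                 points = points, conf = conf, frame_rate = 25),
            class = "trajectory")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("heel-to-heel distance is the per-frame Euclidean distance", {
  l <- make_traj(rbind(c(0, 0), c(1, 1)))
  r <- make_traj(rbind(c(3, 4), c(1, 1)))
  d <- heel_to_heel_distance(l, r)
  expect_equal(d$distance, c(5, 0))
})

test_that("undetected frames are filled by linear interpolation", {
  l <- make_traj(rbind(c(0, 0), c(99, 99), c(0, 0)), conf = c(1, 0, 1))
  r <- make_traj(rbind(c(4, 0), c(0, 0), c(6, 0)))
  d <- heel_to_heel_distance(l, r)
  expect_equal(d$distance[2], 5) # midpoint of 4 and 6
})

test_that("disjoint trajectories raise an empty-overlap error", {
  l <- make_traj(rbind(c(0, 0), c(1, 0)), frames = c(0L, 1L))
  r <- make_traj(rbind(c(0, 0), c(1, 0)), frames = c(5L, 6L))
  expect_error(heel_to_heel_distance(l, r), "empty overlap")
})

test_that("constant series yield no strikes; short series error", {
  expect_identical(detect_heel_strikes(rep(3, 50)), integer(0))
  expect_error(detect_heel_strikes(c(1, 2)), "too short")
})

test_that("planted strikes are recovered exactly without noise", {
  h <- sim_homography()
  gp <- gait_scenario_params(100, heel_strike_frames = c(20, 45, 70),
                             step_period = 25)
  tr <- synth_gait_trajectories(gp, h, rng_seed = 1)
  d <- heel_to_heel_distance(keypoint_trajectory(tr$frames, "LHeel"),
                             keypoint_trajectory(tr$frames, "RHeel"))
  expect_identical(detect_heel_strikes(d), c(20L, 45L, 70L))
})

test_that("strikes stay within one frame of truth at 1 px noise", {
  h <- sim_homography()
  for (seed in 1:4) {
    gp <- gait_scenario_params(100, heel_strike_frames = c(20, 45, 70),
                               step_period = 25, noise_sd = 1)
    tr <- synth_gait_trajectories(gp, h, rng_seed = seed)
    d <- heel_to_heel_distance(keypoint_trajectory(tr$frames, "LHeel"),
                               keypoint_trajectory(tr$frames, "RHeel"))
    det <- detect_heel_strikes(d)
    expect_length(det, 3)
    expect_true(all(abs(det - c(20, 45, 70)) <= 1))
  }
})

test_that("close peaks are pruned keeping the higher one", {
  # brute-force reference on a 30-sample series with peaks 3 frames apart
  s <- rep(0, 30)
  s[10] <- 8
  s[13] <- 10
  det <- detect_heel_strikes(s, min_separation_frames = 10,
                             smoothing_window = 1, min_prominence = 5)
  expect_identical(det, 12L) # 0-based frame of the higher peak
})

test_that("detection is invariant to adding a constant to the series", {
  set.seed(4)
  s <- 20 + 10 * sin(seq(0, 6 * pi, length.out = 120)) + rnorm(120, 0, 0.5)
  expect_identical(detect_heel_strikes(s), detect_heel_strikes(s + 1000))
})

test_that("gait intervals cover the walking stretch only", {
  # stand still for 2 s, walk 2 s, stand still again
  x <- c(rep(0, 50), cumsum(rep(8, 50)), rep(400, 50))
  traj <- make_traj(cbind(x, 100), frames = 0:149)
  iv <- find_gait_intervals(traj, speed_threshold = 30)
  expect_equal(nrow(iv), 1)
  expect_lt(abs(iv$start_frame - 50), 5)
  expect_lt(abs(iv$end_frame - 100), 5)
})
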