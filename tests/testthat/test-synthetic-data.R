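test_that("foot rendering is deterministic and carries its ground truth", {
  p <- foot_scene_params(heel_position = image_point(30, 100),
                         floor_row = 100)
  r1 <- render_foot_image(p, rng_seed = 7)
  r2 <- render_foot_image(p, rng_seed = 7)
  expect_identical(r1$image, r2$image)
  expect_equal(r1$heel, c(x = 30, y = 100))
  expect_equal(dim(r1$image), c(120L, 160L))
  expect_true(all(r1$image >= 0 & r1$image <= 1))
})

test_that("the most posterior floor-contact pixel matches the heel", {
  for (seed in 1:6) {
    hx <- 20 + 7 * seed
    p <- foot_scene_params(heel_position = image_point(hx, 95),
                           floor_row = 95, texture_seed = seed)
    r <- render_foot_image(p)
    contact <- which(r$mask[96, ]) - 1  # 0-based columns on the floor row
    expect_lte(abs(min(contact) - hx), 1)
    # nothing below the floor line
    expect_false(any(r$mask[97:120, ]))
  }
})

test_that("frontal view obeys the same contact-point convention", {
  p <- foot_scene_params(heel_position = image_point(60, 90),
                         floor_row = 90, view = "frontal")
  r <- render_foot_image(p, rng_seed = 2)
  contact <- which(r$mask[91, ]) - 1
  expect_lte(abs(min(contact) - 60), 1)
})

test_that("invalid foot scenes are rejected", {
  expect_error(foot_scene_params(heel_position = image_point(30, 80),
                                 floor_row = 100), "floor line")
  expect_error(foot_scene_params(heel_position = image_point(-5, 100),
                                 floor_row = 100), "outside")
  expect_error(foot_scene_params(foot_length = 200), "foot_length")
})

test_that("gait trajectories plant distance maxima at the strike frames", {
  h <- sim_homography()
  gp <- gait_scenario_params(100, heel_strike_frames = c(20, 45, 70),
                             step_period = 25)
  tr <- synth_gait_trajectories(gp, h, rng_seed = 1)
  expect_length(tr$frames, 100)
  d <- heel_to_heel_distance(keypoint_trajectory(tr$frames, "LHeel"),
                             keypoint_trajectory(tr$frames, "RHeel"))$distance
  for (s in c(20, 45, 70)) {
    i <- s + 1
    expect_gt(d[i], d[i - 1])
    expect_gt(d[i], d[i + 1])
  }
})

test_that("strike world positions step by the configured length and width", {
  h <- sim_homography()
  gp <- gait_scenario_params(100, heel_strike_frames = c(20, 45, 70),
                             step_period = 25, step_length_world = 60,
                             step_width_world = 10)
  tr <- synth_gait_trajectories(gp, h, rng_seed = 1)
  # project planted image heel positions back to the floor at each strike
  for (k in seq_len(nrow(tr$truth$strike_world))) {
    fr <- tr$truth$strike_world$frame[k]
    f <- tr$frames[[fr + 1]]
    heel <- if (tr$truth$strike_world$y[k] < 0) "RHeel" else "LHeel"
    w <- project_to_floor(h, f$keypoints[heel, c("x", "y")])
    expect_equal(unname(w["x"]), tr$truth$strike_world$x[k],
                 tolerance = 1e-6)
  }
  dx <- diff(tr$truth$strike_world$x)
  expect_equal(dx, c(60, 60))
})

test_that("gait generation is reproducible and validates its inputs", {
  h <- sim_homography()
  gp <- gait_scenario_params(80, step_period = 20, noise_sd = 1)
  t1 <- synth_gait_trajectories(gp, h, rng_seed = 3)
  t2 <- synth_gait_trajectories(gp, h, rng_seed = 3)
  expect_identical(t1, t2)
  expect_error(gait_scenario_params(30, step_period = 20), "2 \\* step_period")
  expect_error(gait_scenario_params(100, heel_strike_frames = c(30, 20)),
               "increasing")
})

test_that("noiseless calibration scenes satisfy the projective relation exactly", {
  h <- proj_homography()
  sc <- synth_calibration_scene(h, 5, 0, 2)
  proj <- project_to_floor(h, cbind(sc$img_x, sc$img_y))
  expect_lt(max(abs(proj - cbind(sc$floor_x, sc$floor_y))), 1e-9)
  # identity homography: image coords equal floor coords
  sci <- synth_calibration_scene(diag(3), 5, 0, 2)
  expect_equal(sci$img_x, sci$floor_x, tolerance = 1e-12)
  expect_equal(sci$img_y, sci$floor_y, tolerance = 1e-12)
})

test_that("pose JSON written by the generator loads back loss-free", {
  h <- sim_homography()
  gp <- gait_scenario_params(50, step_period = 20)
  tr <- synth_gait_trajectories(gp, h, rng_seed = 5)
  f <- tempfile(fileext = ".jsonl")
  on.exit(unlink(f))
  write_pose_frames(tr$frames, f)
  back <- load_pose_frames(f)
  expect_length(back, 50)
  expect_equal(back[[10]]$keypoints, tr$frames[[10]]$keypoints,
               tolerance = 1e-12)
})

test_that("foot dataset writer emits crops, annotations and an index", {
  d <- tempfile()
  on.exit(unlink(d, recursive = TRUE))
  samples <- synth_labelled_samples(3, rng_seed = 13)
  write_foot_dataset(samples, d)
  ann <- read.csv(file.path(d, "annotations.csv"))
  expect_equal(nrow(ann), 3)
  expect_named(ann, c("subject_id", "view", "frame", "x", "y"))
  idx <- read.csv(file.path(d, "index.csv"))
  expect_named(idx, c("subject_id", "view", "frame", "origin_x",
                      "origin_y", "path"))
  px <- png::readPNG(file.path(d, idx$path[2]))
  expect_equal(px, samples[[2]]$crop$pixels, tolerance = 1 / 255)
})
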