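make_frame_json <- function(triplets) {
  jsonlite::toJSON(list(version = 1.3,
                        people = list(list(pose_keypoints_2d = triplets))),
                   auto_unbox = TRUE, digits = NA)
}

test_that("BODY_25 triplets pass through to pose frames", {
  kp <- rep(0, 75)
  heel_i <- which(body25_keypoint_names == "RHeel")
  kp[(heel_i - 1) * 3 + 1:3] <- c(70, 160, 0.9)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(make_frame_json(kp), f)
  frames <- load_pose_frames(f)
  expect_length(frames, 1)
  expect_equal(unname(frames[[1]]$keypoints["RHeel", ]), c(70, 160, 0.9))
})

test_that("empty people and malformed records are handled", {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(list(version = 1.3, people = list()),
                              auto_unbox = TRUE), f)
  fr <- load_pose_frames(f)[[1]]
  expect_true(all(fr$keypoints[, "conf"] == 0))

  writeLines(make_frame_json(rep(0, 72)), f) # 24 triplets
  expect_error(load_pose_frames(f), "dialect")

  writeLines("{not json", f)
  expect_error(load_pose_frames(f), "parse error")
})

test_that("per-frame keypoint files in a directory load in order", {
  d <- tempfile()
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  for (i in 0:2) {
    kp <- rep(0, 75)
    kp[1] <- i * 10 # nose x encodes the frame
    writeLines(make_frame_json(kp),
               file.path(d, sprintf("vid_%012d_keypoints.json", i)))
  }
  frames <- load_pose_frames(d)
  expect_equal(vapply(frames, function(f) f$keypoints["Nose", "x"],
                      numeric(1)), c(0, 10, 20))
  expect_equal(vapply(frames, function(f) f$frame_index, integer(1)), 0:2)
})

test_that("foot centroid is the mean of ankle, big toe and heel", {
  kp <- matrix(0, 25, 3,
               dimnames = list(body25_keypoint_names, c("x", "y", "conf")))
  kp["RAnkle", ] <- c(100, 100, 0.9)
  kp["RBigToe", ] <- c(130, 160, 0.8)
  kp["RHeel", ] <- c(70, 160, 0.7)
  fr <- pose_frame(0, kp)
  expect_equal(foot_centroid(fr, "right"), c(x = 100, y = 140))

  # permutation invariance: same three points assigned differently
  kp2 <- kp
  kp2["RAnkle", ] <- c(70, 160, 0.7)
  kp2["RHeel", ] <- c(100, 100, 0.9)
  expect_equal(foot_centroid(pose_frame(0, kp2), "right"),
               foot_centroid(fr, "right"))

  kp["RHeel", "conf"] <- 0
  expect_error(foot_centroid(pose_frame(0, kp), "right"), "missing keypoint")
})

test_that("crop windows center on the centroid and shift at borders", {
  frame <- matrix(runif(1080 * 1920), 1080, 1920)
  cr <- crop_foot(frame, image_point(200, 200))
  expect_equal(cr$origin, c(x = 120, y = 140))
  expect_equal(dim(cr$pixels), c(120L, 160L))

  cr2 <- crop_foot(frame, image_point(30, 30))
  expect_equal(cr2$origin, c(x = 0, y = 0))

  expect_error(crop_foot(matrix(0, 100, 100), image_point(50, 50)),
               "too small")
})

test_that("crop coordinates map back to frame coordinates by the origin", {
  frame <- matrix(0, 400, 600)
  frame[251, 301] <- 1 # marker at 0-based (x = 300, y = 250)
  cr <- crop_foot(frame, image_point(310, 240))
  hit <- which(cr$pixels == 1, arr.ind = TRUE)
  crop_xy <- unname(c(hit[1, 2] - 1, hit[1, 1] - 1))
  expect_equal(crop_xy + c(cr$origin[["x"]], cr$origin[["y"]]), c(300, 250))
})
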