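# Synthetic gait scenarios: 25-keypoint pose trajectories with planted
# heel-strike frames, and calibration scenes with a known homography.
#
# The trajectory model alternates stance plateaus and smoothstep swing
# transitions: the foot that lands at strike k stays planted until the
# other foot lands at strike k+1, then swings monotonically to its next
# contact. With zero noise the heel-to-heel distance therefore has a local
# maximum exactly at every planted strike frame.

#' Parameters of a synthetic gait scenario
#'
#' @param n_frames number of frames.
#' @param frame_rate frames per second (video standard here is 25 Hz).
#' @param step_period frames between successive heel strikes.
#' @param step_length_world step length in cm (floor x between successive
#'   alternating-foot contacts).
#' @param step_width_world step width in cm (floor y between the two feet).
#' @param heel_strike_frames ground-truth strike frames; derived from
#'   `step_period` when omitted.
#' @param noise_sd Gaussian pixel noise added to image keypoints.
#' @return object of class `"gait_scenario_params"`.
#' @export
gait_scenario_params <- function(n_frames, frame_rate = 25, step_period = 25L,
                                 step_length_world = 60,
                                 step_width_world = 10,
                                 heel_strike_frames = NULL, noise_sd = 0) {
  stopifnot(frame_rate > 0, step_period > 0, noise_sd >= 0)
  if (n_frames < 2 * step_period)
    stop("invalid parameters: n_frames must be at least 2 * step_period")
  if (is.null(heel_strike_frames))
    heel_strike_frames <- seq(step_period, n_frames - step_period %/% 2 - 1,
                              by = step_period)
  heel_strike_frames <- as.integer(heel_strike_frames)
  if (length(heel_strike_frames) < 1 ||
      any(diff(heel_strike_frames) <= 0) ||
      any(heel_strike_frames < 0 | heel_strike_frames >= n_frames))
    stop("invalid parameters: heel_strike_frames must be strictly ",
         "increasing within [0, n_frames)")
  structure(list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 step_period = as.integer(step_period),
                 step_length_world = step_length_world,
                 step_width_world = step_width_world,
                 heel_strike_frames = heel_strike_frames,
                 noise_sd = noise_sd),
            class = "gait_scenario_params")
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# World-x position of one foot over time given the strike schedule it owns
# (strikes this foot makes, interleaved with the other foot's). The foot is
# planted at own_x[i] from own_s[i] until the other foot's next strike, then
# swings monotonically (smoothstep) to own_x[i + 1], arriving exactly at
# own_s[i + 1]. Virtual strikes one stride out on both ends close the edges.
foot_world_x <- function(frames, own_s, own_x, other_s, period, stride) {
  # trailing virtual strike far beyond the series, so the final swing never
  # completes in range and cannot plant an extra distance peak
  tail_s <- max(own_s[length(own_s)] + 2 * period, 2 * max(frames) + 2)
  own_s <- c(own_s[1] - 2 * period, own_s, tail_s)
  own_x <- c(own_x[1] - stride, own_x, own_x[length(own_x)] + stride)
  x <- numeric(length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    i <- findInterval(f, own_s)
    if (i == 0) { x[fi] <- own_x[1]; next }
    if (i >= length(own_s)) { x[fi] <- own_x[length(own_x)]; next }
    swing_start <- other_s[other_s > own_s[i] & other_s < own_s[i + 1]]
    swing_start <- if (length(swing_start)) swing_start[1]
                   else (own_s[i] + own_s[i + 1]) / 2
    if (f <= swing_start) {
      x[fi] <- own_x[i]
    } else if (i == length(own_s) - 1) {
      # final (virtual-target) swing: normal timing, but stop at midstance
      # so no further distance peak can form
      u <- (f - swing_start) / (2 * period)
      x[fi] <- own_x[i] +
        (own_x[i + 1] - own_x[i]) * smoothstep(min(u, 0.5))
    } else {
      u <- (f - swing_start) / (own_s[i + 1] - swing_start)
      x[fi] <- own_x[i] + (own_x[i + 1] - own_x[i]) * smoothstep(u)
    }
  }
  x
}

#' Generate synthetic gait pose trajectories
#'
#' @param params a [gait_scenario_params()].
#' @param homography image-to-floor homography used to place keypoints in
#'   the image (world positions are projected through its inverse).
#' @param rng_seed seed for the keypoint noise.
#' @return list with `frames` (list of [pose_frame()] objects) and `truth`
#'   (the params, with resolved strike frames and per-strike world
#'   positions in `truth$strike_world`).
#' @export
synth_gait_trajectories <- function(params, homography, rng_seed = 1L) {
  stopifnot(inherits(params, "gait_scenario_params"))
  h <- as_homography(homography)
  n <- params$n_frames
  strikes <- params$heel_strike_frames
  k <- length(strikes)
  frames <- 0:(n - 1)

  # strike i (1-based) lands at world x0 + (i-1) * step_length; right foot
  # takes odd strikes, left foot even; lateral positions are fixed per foot
  x0 <- 40
  sl <- params$step_length_world
  strike_x <- x0 + (seq_len(k) - 1) * sl
  right_idx <- seq(1, k, by = 2)
  left_idx <- if (k >= 2) seq(2, k, by = 2) else integer(0)

  mk_schedule <- function(own_idx, other_idx) {
    foot_world_x(frames, strikes[own_idx], strike_x[own_idx],
                 strikes[other_idx], params$step_period, stride = 2 * sl)
  }
  rx <- mk_schedule(right_idx, left_idx)
  lx <- if (length(left_idx)) mk_schedule(left_idx, right_idx)
        else rep(strike_x[1] - sl, n)
  ry <- rep(-params$step_width_world / 2, n)
  ly <- rep(params$step_width_world / 2, n)

  r_img <- project_to_image(h, cbind(rx, ry))
  l_img <- project_to_image(h, cbind(lx, ly))
  if (is.null(dim(r_img))) r_img <- matrix(r_img, 1)
  if (is.null(dim(l_img))) l_img <- matrix(l_img, 1)

  with_seed(rng_seed, {
    if (params$noise_sd > 0) {
      r_img <- r_img + stats::rnorm(length(r_img), 0, params$noise_sd)
      l_img <- l_img + stats::rnorm(length(l_img), 0, params$noise_sd)
    }
    out <- vector("list", n)
    for (f in seq_len(n)) {
      kp <- matrix(0, 25, 3,
                   dimnames = list(body25_keypoint_names, c("x", "y", "conf")))
      place <- function(name, x, y) kp[name, ] <<- c(x, y, 0.9)
      place("RHeel", r_img[f, 1], r_img[f, 2])
      place("LHeel", l_img[f, 1], l_img[f, 2])
      place("RBigToe", r_img[f, 1] + 25, r_img[f, 2])
      place("LBigToe", l_img[f, 1] + 25, l_img[f, 2])
      place("RAnkle", r_img[f, 1] + 8, r_img[f, 2] - 14)
      place("LAnkle", l_img[f, 1] + 8, l_img[f, 2] - 14)
      out[[f]] <- pose_frame(f - 1L, kp)
    }
    truth <- params
    truth$strike_world <- data.frame(
      frame = strikes, x = strike_x,
      y = ifelse(seq_len(k) %% 2 == 1, -1, 1) * params$step_width_world / 2)
    list(frames = out, truth = truth)
  })
}

#' Generate a synthetic floor-calibration scene
#'
#' Floor points on a jittered grid (guaranteed non-collinear) are projected
#' into the image through the inverse of `true_h`; optional Gaussian pixel
#' noise is added to the image coordinates.
#'
#' @param true_h the generating homography (image -> floor).
#' @param n_points number of correspondences (>= 4; the field protocol used
#'   five to eight marked points).
#' @param noise_sd image-coordinate noise in px (0 gives exact pairs).
#' @param rng_seed seed.
#' @return data.frame with columns `img_x`, `img_y`, `floor_x`, `floor_y`.
#' @export
synth_calibration_scene <- function(true_h, n_points = 6L, noise_sd = 0,
                                    rng_seed = 1L) {
  if (n_points < 4)
    stop("invalid parameters: need at least 4 calibration points")
  h <- as_homography(true_h)
  with_seed(rng_seed, {
    gx <- c(0, 150, 300, 75, 225, 150, 0, 300)
    gy <- c(-80, 80, -80, 0, 40, -40, 60, 60)
    if (n_points > length(gx)) {
      extra <- n_points - length(gx)
      gx <- c(gx, stats::runif(extra, 0, 300))
      gy <- c(gy, stats::runif(extra, -80, 80))
    }
    fx <- gx[seq_len(n_points)] + c(0, stats::runif(n_points - 1, -5, 5))
    fy <- gy[seq_len(n_points)] + c(0, stats::runif(n_points - 1, -5, 5))
    img <- project_to_image(h, cbind(fx, fy))
    if (is.null(dim(img))) img <- matrix(img, 1)
    if (noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, noise_sd)
    }
    data.frame(img_x = img[, 1], img_y = img[, 2], floor_x = fx, floor_y = fy)
  })
}
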