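# Gait events from heel keypoint trajectories: the heel-strike frame is
# approximated by a peak in the absolute heel-to-heel distance, and gait
# intervals are the stretches where the heel moves at walking speed.

#' Extract a keypoint trajectory from pose frames
#'
#' @param frames list of [pose_frame()] objects.
#' @param keypoint one of [body25_keypoint_names].
#' @param frame_rate frames per second.
#' @return object of class `"trajectory"`: list with `keypoint`, `frames`,
#'   `points` (n x 2), `conf`, `frame_rate`.
#' @export
keypoint_trajectory <- function(frames, keypoint, frame_rate = 25) {
  stopifnot(keypoint %in% body25_keypoint_names)
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  pts <- t(vapply(frames, function(f) f$keypoints[keypoint, c("x", "y")],
                  numeric(2)))
  cf <- vapply(frames, function(f) f$keypoints[keypoint, "conf"], numeric(1))
  o <- order(idx)
  structure(list(keypoint = keypoint, frames = idx[o],
                 points = pts[o, , drop = FALSE], conf = cf[o],
                 frame_rate = frame_rate),
            class = "trajectory")
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Heel-to-heel image distance series
#'
#' Euclidean distance between the left and right heel keypoints per common
#' frame. Frames where either heel is undetected (confidence 0) are filled
#' by linear interpolation from the neighboring valid frames (nearest valid
#' value at the ends).
#'
#' @param left,right `"trajectory"` objects for the two heels.
#' @return data.frame with columns `frame`, `distance` (px).
#' @export
heel_to_heel_distance <- function(left, right) {
  common <- intersect(left$frames, right$frames)
  if (length(common) == 0)
    stop("empty overlap: trajectories share no frames")
  li <- match(common, left$frames)
  ri <- match(common, right$frames)
  d <- sqrt(rowSums((left$points[li, , drop = FALSE] -
                       right$points[ri, , drop = FALSE])^2))
  valid <- left$conf[li] > 0 & right$conf[ri] > 0
  if (!any(valid))
    stop("empty overlap: no frame has both heels detected")
  if (!all(valid)) {
    d[!valid] <- stats::approx(common[valid], d[valid], xout = common[!valid],
                               rule = 2)$y
  }
  data.frame(frame = common, distance = d)
}

# Topographic prominence of peak i in series s: height above the higher of
# the two lowest saddles separating it from higher ground (or from the ends).
peak_prominence <- function(s, i) {
  side_min <- function(idx_seq) {
    m <- s[i]
    for (j in idx_seq) {
      if (s[j] > s[i]) break
      if (s[j] < m) m <- s[j]
    }
    m
  }
  left <- if (i > 1) side_min((i - 1):1) else s[i]
  right <- if (i < length(s)) side_min((i + 1):length(s)) else s[i]
  s[i] - max(left, right)
}

#' Detect heel strikes as peaks of the heel-to-heel distance
#'
#' The series is smoothed with a centered moving average, interior local
#' maxima are found (plateau ties keep the earliest frame), peaks below the
#' prominence floor are dropped, and peaks closer together than the minimum
#' separation are pruned keeping the higher (earlier on equal height).
#'
#' @param distance_series data.frame from [heel_to_heel_distance()] (or a
#'   numeric vector, frames then 0-based positions).
#' @param min_separation_frames minimum frames between reported strikes
#'   (10 frames = 0.4 s at 25 Hz, below any plausible step time).
#' @param smoothing_window moving-average window in frames.
#' @param min_prominence minimum peak prominence in px.
#' @return integer vector of strike frames, ascending.
#' @export
detect_heel_strikes <- function(distance_series, min_separation_frames = 10L,
                                smoothing_window = 3L, min_prominence = 5) {
  if (is.data.frame(distance_series)) {
    fr <- distance_series$frame
    d <- distance_series$distance
  } else {
    d <- as.numeric(distance_series)
    fr <- seq_along(d) - 1L
  }
  n <- length(d)
  if (n <= smoothing_window)
    stop("series too short: length ", n, " with smoothing window ",
         smoothing_window)
  s <- moving_average(d, smoothing_window)

  # interior local maxima; on plateaus keep the earliest frame
  cand <- integer(0)
  i <- 2L
  while (i < n) {
    if (s[i] > s[i - 1]) {
      j <- i
      while (j < n && s[j + 1] == s[i]) j <- j + 1L
      if (j < n && s[j + 1] < s[i]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(cand) == 0) return(integer(0))
  cand <- cand[vapply(cand, function(k) peak_prominence(s, k),
                      numeric(1)) >= min_prominence]
  if (length(cand) == 0) return(integer(0))

  # enforce separation: consider peaks by descending height, earlier first
  # on ties; keep a peak only if far enough from every kept one
  ord <- cand[order(-s[cand], fr[cand])]
  kept <- integer(0)
  for (k in ord) {
    if (all(abs(fr[k] - fr[kept]) >= min_separation_frames))
      kept <- c(kept, k)
  }
  sort(as.integer(fr[kept]))
}

#' Identify gait intervals from a heel trajectory
#'
#' Gait is taken as the stretches where the smoothed forward (image-x) heel
#' speed stays above a threshold for a minimum duration, which separates
#' walking from sitting, standing and turning.
#'
#' @param traj a heel `"trajectory"`.
#' @param speed_threshold minimum speed in px/s.
#' @param min_duration minimum interval length in seconds.
#' @param smoothing_window moving-average window (frames) for the speed.
#' @return data.frame with columns `start_frame`, `end_frame`.
#' @export
find_gait_intervals <- function(traj, speed_threshold = 30,
                                min_duration = 0.5, smoothing_window = 5L) {
  v <- c(0, diff(traj$points[, 1])) * traj$frame_rate
  sp <- moving_average(abs(v), smoothing_window)
  active <- sp > speed_threshold
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_duration * traj$frame_rate
  data.frame(start_frame = traj$frames[starts[keep]],
             end_frame = traj$frames[ends[keep]])
}
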