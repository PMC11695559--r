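# Evaluation in world coordinates: the error that matters for step
# parameters is the distance on the floor between predicted and labelled
# heel points along a single floor axis — the walking (x) axis for the
# side view, the lateral (y) axis for the frontal view. Summaries follow
# the box-plot convention: quartiles, IQR, and outliers beyond 1.5 x IQR
# from the quartiles.

#' Floor-axis prediction error
#'
#' Both points are shifted from crop to full-frame coordinates (adding the
#' crop origin), projected to the floor, and the absolute difference along
#' the relevant floor axis is returned: x (walking direction) for the side
#' view, y (lateral) for the frontal view.
#'
#' @param pred,label image points in crop coordinates.
#' @param crop_origin the crop window origin in the full frame.
#' @param h image-to-floor homography.
#' @param view `"side"` or `"frontal"`.
#' @return error in cm.
#' @export
floor_axis_error <- function(pred, label, crop_origin, h,
                             view = c("side", "frontal")) {
  view <- match.arg(view)
  p <- project_to_floor(h, c(pred[[1]] + crop_origin[[1]],
                             pred[[2]] + crop_origin[[2]]))
  l <- project_to_floor(h, c(label[[1]] + crop_origin[[1]],
                             label[[2]] + crop_origin[[2]]))
  if (view == "side") abs(p[["x"]] - l[["x"]]) else abs(p[["y"]] - l[["y"]])
}

#' Box-plot summary of floor-axis errors
#'
#' Quartiles by linear interpolation of the order statistics (quartile k at
#' rank `k/4 * (n - 1)`, 0-based); outliers are values beyond
#' `q3 + 1.5 * iqr` or below `q1 - 1.5 * iqr`.
#'
#' @param errors numeric vector of errors (cm), length >= 1.
#' @return object of class `"error_summary"`: list with `n`, `min`, `max`,
#'   `median`, `q1`, `q3`, `iqr`, `outlier_fraction`.
#' @export
summarize_errors <- function(errors) {
  if (length(errors) == 0) stop("cannot summarize an empty error vector")
  stopifnot(all(is.finite(errors)))
  q <- stats::quantile(errors, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  out <- errors > q[3] + 1.5 * iqr | errors < q[1] - 1.5 * iqr
  structure(list(n = length(errors), min = min(errors), max = max(errors),
                 median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 outlier_fraction = mean(out)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf(
    "error summary (n = %d):\n  min %.3f  Q1 %.3f  median %.3f  Q3 %.3f  max %.3f\n  IQR %.3f  outlier fraction %.3f\n",
    x$n, x$min, x$q1, x$median, x$q3, x$max, x$iqr, x$outlier_fraction))
  invisible(x)
}

#' @export
format.error_summary <- function(x, ...)
  sprintf("median %.3f cm (Q1 %.3f, Q3 %.3f, n %d)", x$median, x$q1, x$q3,
          x$n)

#' Step length and step width from successive heel contacts
#'
#' Successive heel strikes alternate feet; step length is the absolute
#' floor-x difference and step width the absolute floor-y difference
#' between consecutive contact points.
#'
#' @param heel_floor_points n x 2 matrix (columns floor x, y in cm) of heel
#'   contact points at successive strikes, in time order.
#' @return list with `step_lengths` and `step_widths` (cm, length n - 1).
#' @export
step_parameters <- function(heel_floor_points) {
  p <- as_point_matrix(heel_floor_points)
  if (nrow(p) < 2)
    stop("need at least 2 heel contact points for step parameters")
  list(step_lengths = abs(diff(p[, 1])), step_widths = abs(diff(p[, 2])))
}

#' Heel contact floor points at detected strikes
#'
#' For each strike frame, the heel that just landed is taken as the one
#' farther along the walking axis after projection to the floor.
#'
#' @param frames list of [pose_frame()] objects.
#' @param strike_frames frames from [detect_heel_strikes()].
#' @param h image-to-floor homography.
#' @return matrix (one row per strike) of floor points in cm.
#' @export
strike_floor_points <- function(frames, strike_frames, h) {
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  out <- t(vapply(strike_frames, function(sf) {
    f <- frames[[match(sf, idx)]]
    lp <- project_to_floor(h, f$keypoints["LHeel", c("x", "y")])
    rp <- project_to_floor(h, f$keypoints["RHeel", c("x", "y")])
    if (rp[["x"]] >= lp[["x"]]) rp else lp
  }, numeric(2)))
  colnames(out) <- c("x", "y")
  out
}
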