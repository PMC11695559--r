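# Ingest of 25-keypoint whole-body pose JSON (BODY_25 dialect as written by
# OpenPose: people -> pose_keypoints_2d, flat x, y, confidence triplets),
# foot centroids and fixed-size foot crops.

#' BODY_25 keypoint names
#'
#' Canonical ordering of the 25 whole-body keypoints; the foot keypoints
#' used by the pipeline are `LBigToe`/`RBigToe`, `LHeel`/`RHeel` and
#' `LAnkle`/`RAnkle`.
#' @export
body25_keypoint_names <- c(
  "Nose", "Neck", "RShoulder", "RElbow", "RWrist", "LShoulder", "LElbow",
  "LWrist", "MidHip", "RHip", "RKnee", "RAnkle", "LHip", "LKnee", "LAnkle",
  "REye", "LEye", "REar", "LEar", "LBigToe", "LSmallToe", "LHeel",
  "RBigToe", "RSmallToe", "RHeel")

#' Construct a pose frame
#'
#' @param frame_index 0-based frame number.
#' @param keypoints 25 x 3 matrix (columns x, y, conf) with rows named by
#'   [body25_keypoint_names]. Confidence 0 marks an undetected keypoint
#'   whose coordinates must not be used.
#' @return object of class `"pose_frame"`.
#' @export
pose_frame <- function(frame_index, keypoints) {
  stopifnot(is.matrix(keypoints), nrow(keypoints) == 25,
            ncol(keypoints) == 3)
  rownames(keypoints) <- body25_keypoint_names
  colnames(keypoints) <- c("x", "y", "conf")
  structure(list(frame_index = as.integer(frame_index),
                 keypoints = keypoints),
            class = "pose_frame")
}

parse_people <- function(rec, frame_index, label) {
  people <- rec$people
  if (is.null(people) || length(people) == 0)
    return(pose_frame(frame_index, matrix(0, 25, 3)))
  p <- if (is.data.frame(people)) people$pose_keypoints_2d[[1]]
       else people[[1]]$pose_keypoints_2d
  p <- unlist(p)
  if (length(p) != 75)
    stop("dialect error in ", label, ": expected 25 keypoint triplets, got ",
         length(p) / 3)
  pose_frame(frame_index, matrix(p, 25, 3, byrow = TRUE))
}

#' Load pose frames from BODY_25 JSON
#'
#' Accepts a directory of per-frame `*_keypoints.json` files (sorted by
#' name), a single JSON file holding an array of frame records, or a
#' JSON-lines stream (one frame record per line). Person 0 is taken when
#' several people are present; a frame with no person yields an
#' all-zero-confidence pose frame.
#'
#' @param path directory or file.
#' @return list of [pose_frame()] objects, frame indices 0-based in input
#'   order.
#' @export
load_pose_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "_keypoints\\.json$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no *_keypoints.json files in ", path)
    return(lapply(seq_along(files), function(i) {
      rec <- tryCatch(jsonlite::read_json(files[i]),
                      error = function(e)
                        stop("parse error in ", basename(files[i]), ": ",
                             conditionMessage(e)))
      parse_people(rec, i - 1L, basename(files[i]))
    }))
  }
  txt <- readLines(path, warn = FALSE)
  body <- paste(txt, collapse = "\n")
  if (startsWith(trimws(body), "[")) {
    recs <- jsonlite::fromJSON(body, simplifyVector = FALSE)
  } else {
    txt <- txt[nzchar(trimws(txt))]
    recs <- lapply(seq_along(txt), function(i)
      tryCatch(jsonlite::fromJSON(txt[i], simplifyVector = FALSE),
               error = function(e)
                 stop("parse error in frame ", i - 1, ": ",
                      conditionMessage(e))))
  }
  lapply(seq_along(recs), function(i)
    parse_people(recs[[i]], i - 1L, paste0("frame ", i - 1)))
}

#' Write pose frames as a BODY_25 JSON-lines stream
#' @param frames list of [pose_frame()] objects.
#' @param path output file.
#' @export
write_pose_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    rec <- list(version = 1.3,
                people = list(list(pose_keypoints_2d =
                                     as.vector(t(fr$keypoints)))))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Foot centroid of a pose frame
#'
#' Arithmetic mean of the ankle, big-toe and heel keypoints of one foot,
#' used to center the fixed-size foot crop.
#'
#' @param frame a [pose_frame()].
#' @param side_of_body `"left"` or `"right"`.
#' @return image point.
#' @export
foot_centroid <- function(frame, side_of_body = c("left", "right")) {
  side_of_body <- match.arg(side_of_body)
  pre <- if (side_of_body == "left") "L" else "R"
  names <- paste0(pre, c("Ankle", "BigToe", "Heel"))
  kp <- frame$keypoints[names, , drop = FALSE]
  if (any(kp[, "conf"] == 0))
    stop("missing keypoint: ",
         paste(names[kp[, "conf"] == 0], collapse = ", "),
         " undetected (confidence 0) in frame ", frame$frame_index)
  image_point(mean(kp[, "x"]), mean(kp[, "y"]))
}

#' Crop a fixed-size foot image
#'
#' Extracts the standard 160 x 120 window centered at the rounded centroid
#' (origin = centroid - (80, 60)). Windows that would cross a frame edge
#' are shifted by the minimal amount to fit, so no padding is introduced;
#' the recorded origin maps crop coordinates back to frame coordinates by
#' addition.
#'
#' @param full_frame image matrix (H x W) or array (H x W x C) with 0-based
#'   pixel coordinates.
#' @param centroid image point to center on.
#' @param view `"side"` or `"frontal"`.
#' @param side_of_body `"left"` or `"right"`.
#' @param subject_id,frame_index provenance.
#' @return object of class `"foot_crop"` with fields `pixels`, `origin`,
#'   `view`, `side_of_body`, `subject_id`, `frame_index`.
#' @export
crop_foot <- function(full_frame, centroid, view = "side",
                      side_of_body = "right", subject_id = NA,
                      frame_index = NA) {
  d <- dim(full_frame)
  fh <- d[1]; fw <- d[2]
  if (fh < CROP_H || fw < CROP_W)
    stop("frame too small: need at least ", CROP_W, " x ", CROP_H,
         " pixels, got ", fw, " x ", fh)
  ox <- round(centroid[["x"]]) - CROP_W %/% 2
  oy <- round(centroid[["y"]]) - CROP_H %/% 2
  ox <- min(max(ox, 0), fw - CROP_W)
  oy <- min(max(oy, 0), fh - CROP_H)
  rows <- (oy + 1):(oy + CROP_H)
  cols <- (ox + 1):(ox + CROP_W)
  px <- if (length(d) == 2) full_frame[rows, cols]
        else full_frame[rows, cols, , drop = FALSE]
  structure(list(pixels = px, origin = image_point(ox, oy), view = view,
                 side_of_body = side_of_body, subject_id = subject_id,
                 frame_index = frame_index),
            class = "foot_crop")
}
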