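# Synthetic foot scenes: textured silhouettes with an exactly known heel
# contact point. These stand in for cropped video frames so that keypoint
# networks, augmentation and evaluation can be exercised without clinical
# recordings. The rendering is deliberately schematic — the test surface is
# keypoint recovery, not photorealism — but varied enough (textures,
# intensities, shape jitter) that a network must localize the silhouette.

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters of a synthetic foot scene
#'
#' @param image_width,image_height scene size in px (the standard crop is
#'   160 x 120; larger "virtual frames" let augmentation re-crop without
#'   padding).
#' @param foot_length,foot_height silhouette size in px.
#' @param heel_position image point of the heel: the most posterior (side
#'   view) or most lateral (frontal view) floor-contact point. Its y must
#'   equal `floor_row`.
#' @param floor_row image row of the floor line.
#' @param texture_seed integer seed for textures and shape jitter.
#' @param view `"side"` or `"frontal"`.
#' @return object of class `"foot_scene_params"`.
#' @export
foot_scene_params <- function(image_width = 160L, image_height = 120L,
                              foot_length = 70, foot_height = 28,
                              heel_position = image_point(45, 95),
                              floor_row = 95, texture_seed = 1L,
                              view = c("side", "frontal")) {
  view <- match.arg(view)
  if (heel_position[["y"]] != floor_row)
    stop("invalid parameters: heel_position must lie on the floor line ",
         "(heel y = ", heel_position[["y"]], ", floor_row = ", floor_row, ")")
  if (heel_position[["x"]] < 0 || heel_position[["x"]] >= image_width ||
      heel_position[["y"]] < 0 || heel_position[["y"]] >= image_height)
    stop("invalid parameters: heel_position outside the image")
  if (foot_length <= 0 || foot_length >= image_width)
    stop("invalid parameters: need 0 < foot_length < image_width")
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 foot_length = foot_length, foot_height = foot_height,
                 heel_position = heel_position, floor_row = floor_row,
                 texture_seed = as.integer(texture_seed), view = view),
            class = "foot_scene_params")
}

# Smooth random texture in [-1, 1]: low-resolution uniform noise, bilinearly
# upsampled.
smooth_noise <- function(h, w, cell = 8) {
  gh <- ceiling(h / cell) + 1
  gw <- ceiling(w / cell) + 1
  g <- matrix(stats::runif(gh * gw, -1, 1), gh, gw)
  yi <- (seq_len(h) - 1) / cell
  xi <- (seq_len(w) - 1) / cell
  y0 <- pmin(floor(yi), gh - 2); fy <- yi - y0
  x0 <- pmin(floor(xi), gw - 2); fx <- xi - x0
  a <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  b <- g[cbind(rep(y0 + 2, w), rep(x0 + 1, each = h))]
  cc <- g[cbind(rep(y0 + 1, w), rep(x0 + 2, each = h))]
  d <- g[cbind(rep(y0 + 2, w), rep(x0 + 2, each = h))]
  fy <- rep(fy, w); fx <- rep(fx, each = h)
  m <- a * (1 - fy) * (1 - fx) + b * fy * (1 - fx) +
    cc * (1 - fy) * fx + d * fy * fx
  matrix(m, h, w)
}

#' Render a synthetic foot image
#'
#' Draws a foot-like silhouette (a superellipse dome whose floor-contact
#' span starts exactly at the heel, plus a leg band) over textured
#' background and floor. The most posterior (side view) / most lateral
#' (frontal view) silhouette pixel on the floor row coincides with the
#' requested heel position by construction.
#'
#' @param params a [foot_scene_params()].
#' @param rng_seed seed for textures and shape jitter; defaults to the
#'   params' `texture_seed`.
#' @return list with `image` (height x width matrix, grayscale in `[0, 1]`),
#'   `heel` (the ground-truth image point, equal to
#'   `params$heel_position`), and `mask` (logical silhouette matrix).
#' @export
render_foot_image <- function(params, rng_seed = params$texture_seed) {
  stopifnot(inherits(params, "foot_scene_params"))
  w <- params$image_width; h <- params$image_height
  hx <- params$heel_position[["x"]]; fr <- params$floor_row
  len <- if (params$view == "side") params$foot_length
         else 0.6 * params$foot_length
  if (hx + len >= w)
    stop("invalid parameters: foot extends beyond the image")
  with_seed(rng_seed, {
    x <- matrix(rep(0:(w - 1), each = h), h, w)
    y <- matrix(rep(0:(h - 1), w), h, w)

    # dome: |dx/a|^e + |dy/b|^e <= 1, centered on the floor line so the
    # contact span is exactly [hx, hx + len] whatever the exponent
    a <- len / 2
    b <- params$foot_height * stats::runif(1, 0.85, 1.15)
    e <- stats::runif(1, 1.8, 2.8)
    cx <- hx + a
    mask <- y <= fr &
      (abs((x - cx) / a)^e + abs((y - fr) / b)^e) <= 1

    # leg band rising from the mid foot; stays off the floor line
    legw <- len * stats::runif(1, 0.22, 0.3)
    slope <- tan(stats::runif(1, -5, 5) * pi / 180)
    lx <- cx + stats::runif(1, -0.1, 0.1) * a
    leg_top <- max(0, fr - params$foot_height - stats::runif(1, 20, 60))
    leg <- y >= leg_top & y <= fr - 0.4 * b &
      abs(x - (lx + slope * (fr - y))) <= legw / 2
    mask <- mask | (leg & y <= fr - 2)

    bg <- 0.72 + 0.12 * smooth_noise(h, w, 10) +
      0.04 * stats::rnorm(1)
    floor_tex <- 0.5 + 0.1 * smooth_noise(h, w, 6)
    img <- ifelse(y > fr, floor_tex, bg)
    foot_tex <- 0.22 + 0.08 * smooth_noise(h, w, 5) +
      0.03 * stats::rnorm(1)
    img[mask] <- foot_tex[mask]
    img <- img + 0.02 * matrix(stats::rnorm(h * w), h, w)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, heel = image_point(hx, fr), mask = mask)
  })
}

#' Write foot crops and annotations to disk
#'
#' Crops are written as PNG, labels as a CSV with columns
#' `subject_id, view, frame, x, y`.
#' @param samples list of labelled samples (see [synth_labelled_samples()]).
#' @param dir output directory (created if needed).
#' @return the annotation data.frame, invisibly.
#' @export
write_foot_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- do.call(rbind, lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    path <- file.path(dir, sprintf("crop_%05d.png", i))
    png::writePNG(s$crop$pixels, path)
    data.frame(subject_id = s$crop$subject_id, view = s$crop$view,
               frame = s$crop$frame_index, x = s$heel[["x"]],
               y = s$heel[["y"]], origin_x = s$crop$origin[["x"]],
               origin_y = s$crop$origin[["y"]], path = basename(path))
  }))
  utils::write.csv(ann[, c("subject_id", "view", "frame", "x", "y")],
                   file.path(dir, "annotations.csv"), row.names = FALSE)
  utils::write.csv(ann[, c("subject_id", "view", "frame", "origin_x",
                           "origin_y", "path")],
                   file.path(dir, "index.csv"), row.names = FALSE)
  invisible(ann)
}
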