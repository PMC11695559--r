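# Floor-plane calibration: estimating the image<->floor homography from
# marked floor points and projecting points between the two planes.
#
# Conventions: image points are (x, y) in pixels, x rightward along columns,
# y downward along rows, sub-pixel, 0-based. Floor points are (x, y) in
# centimeters, x along the walking axis (chair -> 3-m line), y to the left
# as seen from the chair.

#' Construct an image point
#' @param x,y pixel coordinates (column, row); sub-pixel allowed.
#' @return named numeric vector of length 2.
#' @export
image_point <- function(x, y) {
  stopifnot(is.finite(x), is.finite(y))
  c(x = as.numeric(x), y = as.numeric(y))
}

#' Construct a floor point
#' @param x,y floor coordinates in cm (walking axis, leftward axis).
#' @return named numeric vector of length 2.
#' @export
floor_point <- function(x, y) {
  stopifnot(is.finite(x), is.finite(y))
  c(x = as.numeric(x), y = as.numeric(y))
}

as_point_matrix <- function(p) {
  if (is.matrix(p)) return(p)
  matrix(p, ncol = 2, byrow = TRUE)
}

#' Estimate the image-to-floor homography
#'
#' Normalized direct linear transform (DLT): both point sets are translated
#' to their centroid and scaled to mean distance sqrt(2) (Hartley
#' normalization), the 2n x 9 design matrix is assembled and its SVD null
#' vector gives the homography, which is then denormalized and scaled so
#' that `h[3, 3] == 1`. Exact (residual ~ machine precision) for consistent
#' noiseless correspondences.
#'
#' @param pairs a data.frame with columns `img_x`, `img_y`, `floor_x`,
#'   `floor_y`, one row per marked floor point (at least 4).
#' @return a 3x3 matrix of class `"homography"` mapping homogeneous image
#'   coordinates to floor coordinates.
#' @export
estimate_homography <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("img_x", "img_y", "floor_x", "floor_y")
  stopifnot(all(need %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 4)
    stop("insufficient correspondences: need at least 4 point pairs, got ", n)
  src <- cbind(pairs$img_x, pairs$img_y)
  dst <- cbind(pairs$floor_x, pairs$floor_y)

  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    t_mat <- rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
    list(p = sweep(p, 2, ctr) * s, t = t_mat)
  }
  ns <- norm_pts(src)
  nd <- norm_pts(dst)

  a <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- ns$p[i, 1]; y <- ns$p[i, 2]
    u <- nd$p[i, 1]; v <- nd$p[i, 2]
    a[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    a[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(a, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * max(sv$d[1], .Machine$double.eps))
    stop("degenerate configuration: floor points do not determine a unique ",
         "homography (collinear or coincident points)")
  h <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  h <- solve(nd$t) %*% h %*% ns$t
  if (abs(h[3, 3]) < 1e-14 || abs(det(h)) < 1e-14)
    stop("degenerate configuration: estimated homography is singular")
  h <- h / h[3, 3]
  structure(h, class = "homography")
}

as_homography <- function(h) {
  h <- unclass(h)
  stopifnot(is.matrix(h), all(dim(h) == 3))
  if (abs(det(h)) < 1e-14) stop("homography matrix is singular")
  structure(h / h[3, 3], class = "homography")
}

project_homog <- function(h, p) {
  p <- as_point_matrix(p)
  ph <- cbind(p, 1) %*% t(unclass(h))
  w <- ph[, 3]
  if (any(abs(w) < 1e-12))
    stop("point at infinity: projection has vanishing homogeneous component")
  out <- ph[, 1:2, drop = FALSE] / w
  colnames(out) <- c("x", "y")
  if (nrow(out) == 1) c(x = unname(out[1, 1]), y = unname(out[1, 2]))
  else out
}

#' Project image points onto the floor plane
#' @param h a `"homography"` from [estimate_homography()].
#' @param p image point (length-2 vector) or n x 2 matrix.
#' @return floor point(s) in cm, same shape as the input.
#' @export
project_to_floor <- function(h, p) project_homog(as_homography(h), p)

#' Project floor points into the image
#'
#' Exact inverse of [project_to_floor()] up to floating-point round-off.
#' @inheritParams project_to_floor
#' @param q floor point (length-2 vector) or n x 2 matrix, in cm.
#' @export
project_to_image <- function(h, q) {
  hi <- solve(unclass(as_homography(h)))
  project_homog(structure(hi / hi[3, 3], class = "homography"), q)
}

#' Read floor-calibration correspondences
#'
#' Whitespace-separated columns `img_x img_y floor_x floor_y`; `#` starts a
#' comment.
#' @param path file path.
#' @return data.frame suitable for [estimate_homography()].
#' @export
read_correspondences <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("img_x", "img_y", "floor_x", "floor_y"))
  d
}

#' Write floor-calibration correspondences
#' @param pairs data.frame with `img_x`, `img_y`, `floor_x`, `floor_y`.
#' @param path file path.
#' @export
write_correspondences <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# img_x img_y floor_x floor_y", con)
  utils::write.table(pairs[, c("img_x", "img_y", "floor_x", "floor_y")],
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a homography as JSON (row-major 3x3, h33 = 1)
#' @param h homography.
#' @param path output path.
#' @export
write_homography_json <- function(h, path) {
  h <- unclass(as_homography(h))
  jsonlite::write_json(list(h = as.vector(t(h))), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a homography written by [write_homography_json()]
#' @param path JSON path.
#' @export
read_homography_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)$h
  as_homography(matrix(v, 3, 3, byrow = TRUE))
}
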