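# Labelled foot-crop samples, the augmentation scheme (20 random
# translations of the crop window, each also flipped horizontally, i.e.
# x40 per original) and subject-wise train/validation/test splitting.

#' Construct a labelled sample
#'
#' @param crop a `"foot_crop"`.
#' @param heel image point of the heel in crop coordinates.
#' @param flipped,translation augmentation provenance (defaults: original).
#' @return object of class `"labelled_sample"`.
#' @export
labelled_sample <- function(crop, heel, flipped = FALSE,
                            translation = c(0L, 0L)) {
  if (heel[["x"]] < 0 || heel[["x"]] > CROP_W - 1 ||
      heel[["y"]] < 0 || heel[["y"]] > CROP_H - 1)
    stop("heel label outside the ", CROP_W, " x ", CROP_H, " crop")
  structure(list(crop = crop, heel = heel, flipped = flipped,
                 translation = as.integer(translation)),
            class = "labelled_sample")
}

# Extract a crop window from a frame, replicating edge pixels where the
# window leaves the frame.
window_with_replication <- function(frame, ox, oy) {
  d <- dim(frame)
  rows <- pmin(pmax((oy + 1):(oy + CROP_H), 1), d[1])
  cols <- pmin(pmax((ox + 1):(ox + CROP_W), 1), d[2])
  if (length(d) == 2) frame[rows, cols] else frame[rows, cols, , drop = FALSE]
}

flip_pixels <- function(px) {
  if (length(dim(px)) == 2) px[, ncol(px):1]
  else px[, dim(px)[2]:1, , drop = FALSE]
}

#' Augment a labelled sample
#'
#' Applies `n_translations` random shifts of the crop window, each drawn
#' per axis independently and uniformly from the integers in
#' `[-translation_width/2, translation_width/2]`, re-cropping from the
#' source frame so no padding enters the data; each translated crop is also
#' flipped horizontally when `flip` is on. The originals are not included,
#' so the yield is `n_translations * 2` samples per input (the x40 scheme:
#' 20 translations, each flipped).
#'
#' A shifted window that would leave the source frame falls back to
#' edge-replication padding with a warning (synthetic virtual frames are
#' sized so this does not happen).
#'
#' @param sample a [labelled_sample()].
#' @param source_frame the full frame the crop was taken from.
#' @param n_translations number of random shifts (20 as published).
#' @param translation_width full width of the uniform shift distribution in
#'   px (60 as published, i.e. shifts in `[-30, 30]`).
#' @param flip also mirror each translated crop horizontally.
#' @param rng_seed seed for the shift draws.
#' @return list of `n_translations * (1 + flip)` labelled samples.
#' @export
augment <- function(sample, source_frame, n_translations = 20L,
                    translation_width = 60L, flip = TRUE, rng_seed = 1L) {
  stopifnot(inherits(sample, "labelled_sample"))
  d <- dim(source_frame)
  half <- translation_width %/% 2
  org <- sample$crop$origin
  with_seed(rng_seed, {
    out <- vector("list", n_translations * (1L + as.integer(flip)))
    oi <- 1L
    for (t in seq_len(n_translations)) {
      dx <- sample.int(2L * half + 1L, 1L) - half - 1L
      dy <- sample.int(2L * half + 1L, 1L) - half - 1L
      ox <- org[["x"]] + dx
      oy <- org[["y"]] + dy
      if (ox < 0 || oy < 0 || ox + CROP_W > d[2] || oy + CROP_H > d[1]) {
        warning("shifted crop window leaves the source frame; ",
                "using edge replication")
      }
      px <- window_with_replication(source_frame, ox, oy)
      crop <- sample$crop
      crop$pixels <- px
      crop$origin <- image_point(ox, oy)
      heel <- image_point(sample$heel[["x"]] - dx, sample$heel[["y"]] - dy)
      out[[oi]] <- labelled_sample(crop, heel, flipped = FALSE,
                                   translation = c(dx, dy))
      oi <- oi + 1L
      if (flip) {
        fcrop <- crop
        fcrop$pixels <- flip_pixels(px)
        fheel <- image_point(CROP_W - 1 - heel[["x"]], heel[["y"]])
        out[[oi]] <- labelled_sample(fcrop, fheel, flipped = TRUE,
                                     translation = c(dx, dy))
        oi <- oi + 1L
      }
    }
    out
  })
}

#' Subject-wise split specification
#'
#' @param n_train,n_val,n_test subject counts per split (the study used
#'   157 / 9 / 18 of 184 subjects).
#' @param seed shuffle seed.
#' @export
split_spec <- function(n_train, n_val, n_test, seed = 1L) {
  stopifnot(n_train > 0, n_val > 0, n_test > 0)
  structure(list(n_train = n_train, n_val = n_val, n_test = n_test,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split samples by subject
#'
#' Subjects are shuffled with the spec's seed and partitioned; every sample
#' of a subject (originals and augmentations alike) lands in exactly one
#' split, so no subject leaks across splits.
#'
#' @param samples list of labelled samples.
#' @param spec a [split_spec()].
#' @return list with elements `train`, `val`, `test` (lists of samples) and
#'   `subjects` (the per-split subject ids).
#' @export
split_by_subject <- function(samples, spec) {
  stopifnot(inherits(spec, "split_spec"))
  subj <- vapply(samples, function(s) as.character(s$crop$subject_id),
                 character(1))
  ids <- sort(unique(subj))
  total <- spec$n_train + spec$n_val + spec$n_test
  if (length(ids) != total)
    stop("invalid spec: split counts sum to ", total, " but there are ",
         length(ids), " distinct subjects")
  shuffled <- with_seed(spec$seed, base::sample(ids))
  grp <- list(train = shuffled[seq_len(spec$n_train)],
              val = shuffled[spec$n_train + seq_len(spec$n_val)],
              test = shuffled[spec$n_train + spec$n_val +
                                seq_len(spec$n_test)])
  list(train = samples[subj %in% grp$train],
       val = samples[subj %in% grp$val],
       test = samples[subj %in% grp$test],
       subjects = grp)
}

#' Generate labelled synthetic foot samples
#'
#' Renders foot scenes in a larger virtual frame (so augmentation can shift
#' the crop window without padding) and crops the standard 160 x 120 window
#' with the heel at a random interior position.
#'
#' @param n number of samples.
#' @param rng_seed seed.
#' @param view `"side"` or `"frontal"`.
#' @param frame_w,frame_h virtual frame size (>= 280 x 240 leaves room for
#'   the +-30 px augmentation shifts).
#' @param samples_per_subject consecutive samples sharing a subject id.
#' @param keep_frames keep each source frame in the result (needed by
#'   [augment()]); turn off to save memory.
#' @return list of [labelled_sample()] objects; each has the source frame
#'   attached as attribute `"source_frame"` when `keep_frames` is on.
#' @export
synth_labelled_samples <- function(n, rng_seed = 1L, view = "side",
                                   frame_w = 320L, frame_h = 240L,
                                   samples_per_subject = 8L,
                                   keep_frames = FALSE) {
  draws <- with_seed(rng_seed, {
    data.frame(
      heel_x = round(stats::runif(n, 80, frame_w - 110)),
      floor_row = round(stats::runif(n, 120, frame_h - 62)),
      foot_len = stats::runif(n, 55, 85),
      foot_h = stats::runif(n, 22, 34),
      tx = round(stats::runif(n, 31, 125)),
      ty = round(stats::runif(n, 35, 88)),
      seed = sample.int(.Machine$integer.max %/% 2, n))
  })
  lapply(seq_len(n), function(i) {
    p <- foot_scene_params(
      image_width = frame_w, image_height = frame_h,
      foot_length = draws$foot_len[i], foot_height = draws$foot_h[i],
      heel_position = image_point(draws$heel_x[i], draws$floor_row[i]),
      floor_row = draws$floor_row[i], texture_seed = draws$seed[i],
      view = view)
    sc <- render_foot_image(p)
    # keep the crop window >= 30 px from every frame edge (so the +-30 px
    # augmentation shifts never need padding) and the heel label >= 30 px
    # inside the crop (so shifted labels stay inside it too)
    tx <- min(max(draws$tx[i], max(31, draws$heel_x[i] - (frame_w - CROP_W - 30))),
              min(125, draws$heel_x[i] - 30))
    ty <- min(max(draws$ty[i], max(35, draws$floor_row[i] - (frame_h - CROP_H - 30))),
              min(88, draws$floor_row[i] - 30))
    ox <- draws$heel_x[i] - tx
    oy <- draws$floor_row[i] - ty
    crop <- crop_foot(sc$image, image_point(ox + CROP_W %/% 2,
                                            oy + CROP_H %/% 2),
                      view = view, side_of_body = "right",
                      subject_id = sprintf("S%04d",
                                           (i - 1) %/% samples_per_subject + 1),
                      frame_index = i)
    s <- labelled_sample(crop, image_point(draws$heel_x[i] - ox,
                                           draws$floor_row[i] - oy))
    if (keep_frames) attr(s, "source_frame") <- sc$image
    s
  })
}

#' Write a dataset split manifest
#'
#' JSON recording which subjects belong to each split and the augmentation
#' provenance fields stored per sample, so a training corpus can be
#' reconstructed exactly.
#'
#' @param split result of [split_by_subject()].
#' @param path output JSON path.
#' @param augmentation optional list describing the augmentation applied
#'   (e.g. `list(n_translations = 20, translation_width = 60, flip = TRUE)`).
#' @export
write_split_manifest <- function(split, path, augmentation = NULL) {
  m <- list(subjects = split$subjects,
            n_samples = list(train = length(split$train),
                             val = length(split$val),
                             test = length(split$test)))
  if (!is.null(augmentation)) m$augmentation <- augmentation
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write heel keypoint annotations
#'
#' CSV with columns `subject_id, view, frame, side_of_body, x, y`
#' (integer-pixel labels; sub-pixel labels are allowed in memory).
#' @param annotations data.frame in that column layout.
#' @param path CSV path.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
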