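test_that("augmentation yields translations x flip and exact label shifts", {
  s <- fixture_sample()
  frame <- attr(s, "source_frame")
  aug <- augment(s, frame, n_translations = 20, flip = TRUE, rng_seed = 9)
  expect_length(aug, 40)

  for (a in aug) {
    dx <- a$translation[1]; dy <- a$translation[2]
    expect_true(all(abs(c(dx, dy)) <= 30))
    if (!a$flipped) {
      expect_equal(a$heel[["x"]], s$heel[["x"]] - dx)
    } else {
      expect_equal(a$heel[["x"]], 159 - (s$heel[["x"]] - dx))
    }
    expect_equal(a$heel[["y"]], s$heel[["y"]] - dy)
    # label inversion recovers the original exactly (integer arithmetic)
    hx <- a$heel[["x"]]
    if (a$flipped) hx <- 159 - hx
    expect_identical(hx + dx, s$heel[["x"]])
    expect_identical(a$heel[["y"]] + dy, s$heel[["y"]])
  }
  # no flip halves the yield
  expect_length(augment(s, frame, n_translations = 20, flip = FALSE,
                        rng_seed = 9), 20)
})

test_that("augmented crops are re-cropped from the frame, pixels intact", {
  s <- fixture_sample(seed = 11)
  frame <- attr(s, "source_frame")
  a <- augment(s, frame, n_translations = 3, flip = TRUE, rng_seed = 2)[[1]]
  ox <- a$crop$origin[["x"]]; oy <- a$crop$origin[["y"]]
  expect_identical(a$crop$pixels,
                   frame[(oy + 1):(oy + 120), (ox + 1):(ox + 160)])
})

test_that("flipping mirrors pixels around the vertical axis", {
  s <- fixture_sample(seed = 3)
  frame <- attr(s, "source_frame")
  aug <- augment(s, frame, n_translations = 1, flip = TRUE, rng_seed = 5)
  expect_identical(aug[[2]]$crop$pixels, aug[[1]]$crop$pixels[, 160:1])
})

test_that("augmentation is deterministic under a fixed seed", {
  s <- fixture_sample(seed = 7)
  frame <- attr(s, "source_frame")
  a1 <- augment(s, frame, rng_seed = 31)
  a2 <- augment(s, frame, rng_seed = 31)
  expect_identical(a1, a2)
})

test_that("subject split partitions all subjects without leakage", {
  samples <- synth_labelled_samples(60, rng_seed = 21,
                                    samples_per_subject = 3)
  spec <- split_spec(14, 2, 4, seed = 8)
  sp <- split_by_subject(samples, spec)
  expect_length(sp$subjects$train, 14)
  expect_length(sp$subjects$val, 2)
  expect_length(sp$subjects$test, 4)
  expect_length(intersect(sp$subjects$train, sp$subjects$val), 0)
  expect_length(intersect(sp$subjects$train, sp$subjects$test), 0)
  expect_length(intersect(sp$subjects$val, sp$subjects$test), 0)
  expect_equal(length(sp$train) + length(sp$val) + length(sp$test), 60)

  sp2 <- split_by_subject(samples, spec)
  expect_identical(sp$subjects, sp2$subjects)

  expect_error(split_by_subject(samples, split_spec(10, 2, 4, 8)),
               "invalid spec")
})

test_that("heel labels must lie inside the crop", {
  s <- fixture_sample()
  expect_error(labelled_sample(s$crop, image_point(200, 50)), "outside")
})

test_that("annotation CSV round trips", {
  ann <- data.frame(subject_id = c("S1", "S2"), view = "side",
                    frame = c(3L, 9L), side_of_body = "right",
                    x = c(45L, 52L), y = c(90L, 88L))
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_annotations(ann, f)
  expect_equal(read_annotations(f), ann)
})

test_that("split manifests record membership and augmentation provenance", {
  samples <- synth_labelled_samples(24, rng_seed = 5,
                                    samples_per_subject = 4)
  sp <- split_by_subject(samples, split_spec(4, 1, 1, seed = 2))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_split_manifest(sp, f, augmentation = list(n_translations = 20,
                                                  translation_width = 60,
                                                  flip = TRUE))
  m <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(sort(m$subjects$train), sort(sp$subjects$train))
  expect_equal(m$n_samples$train, length(sp$train))
  expect_equal(m$augmentation$n_translations, 20)
})
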