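test_that("parameter counts match the published architectures", {
  # regression head alone: (1000 + 1) * 2
  head_only <- nn_linear(1000L, 2L)
  expect_identical(nn_count_parameters(head_only), 2002L)

  vgg <- build_model(model_spec("vgg19", "regression"), init = FALSE)
  expect_identical(count_parameters(vgg), 143667240L + 2002L)
  mnv2 <- build_model(model_spec("mobilenetv2", "regression"), init = FALSE)
  expect_identical(count_parameters(mnv2), 3504872L + 2002L)
  rx <- build_model(model_spec("resnext50", "regression"), init = FALSE)
  expect_identical(count_parameters(rx), 25028904L + 2002L)
})

test_that("heatmap variants output a single near-input-resolution channel", {
  m <- build_model(model_spec("mobilenetv2", "heatmap", width_mult = 0.35),
                   init = FALSE)
  expect_equal(m$out_hw, c(128L, 160L))
  # each dimension within a factor 2 of the input
  expect_true(all(m$out_hw >= c(120, 160) / 2 & m$out_hw <= c(120, 160) * 2))
  v <- build_model(model_spec("vgg19", "heatmap"), init = FALSE)
  expect_true(all(v$out_hw >= c(120, 160) / 2 & v$out_hw <= c(120, 160) * 2))
})

test_that("a small heatmap model forward pass has the declared shape", {
  m <- build_model(model_spec("mobilenetv2", "heatmap", width_mult = 0.25,
                              head_channels = c(16, 8, 8, 4, 4)), seed = 2)
  x <- array(runif(120 * 160 * 3 * 2), c(120, 160, 3, 2))
  y <- nn_forward(m$net, x, training = FALSE)
  expect_equal(dim(y), c(m$out_hw[1], m$out_hw[2], 1L, 2L))
})

test_that("unknown architecture enums are rejected", {
  expect_error(model_spec("alexnet", "regression"))
  expect_error(model_spec("vgg19", "softmax"))
})

test_that("target heatmaps are unit-peak Gaussians", {
  hm <- render_target_heatmap(c(80, 60), c(120, 160), sigma = 3)
  expect_equal(which(hm == max(hm), arr.ind = TRUE)[1, ],
               c(row = 61, col = 81))
  expect_equal(max(hm), 1)
  expect_equal(hm[61, 81 + 3], exp(-1 / 2), tolerance = 1e-12)
  expect_equal(hm[61 - 3, 81], exp(-1 / 2), tolerance = 1e-12)
  # tiny sigma concentrates all mass in one pixel
  hm2 <- render_target_heatmap(c(80, 60), c(120, 160), sigma = 0.1)
  expect_equal(sum(hm2), 1, tolerance = 1e-6)
  expect_error(render_target_heatmap(c(80, 60), c(120, 160), sigma = 0),
               "sigma")
})

test_that("heatmap decoding recovers sub-pixel keypoints", {
  hm <- matrix(0, 120, 160)
  hm[11, 11] <- 1 # 0-based (10, 10)
  expect_equal(decode_heatmap(hm), c(x = 10, y = 10))

  for (pt in list(c(45.25, 30.75), c(80.5, 60.1), c(12, 100))) {
    hm <- render_target_heatmap(pt, c(120, 160), sigma = 3)
    dec <- decode_heatmap(hm)
    expect_lt(max(abs(dec - c(x = pt[1], y = pt[2]))), 0.1)
  }
})

test_that("decoding ties anchor at the first row-major maximum", {
  hm <- matrix(0, 20, 20)
  hm[6, 6] <- 1 # (5, 5) 0-based
  hm[6, 7] <- 1 # (6, 5)
  expect_equal(decode_heatmap(hm), c(x = 5.5, y = 5))
})

test_that("decoding is equivariant to horizontal flips", {
  for (seed in 1:4) {
    set.seed(seed)
    hm <- render_target_heatmap(c(runif(1, 10, 150), runif(1, 10, 110)),
                                c(120, 160), sigma = 3)
    hm <- unclass(hm) + 0.01 * matrix(runif(120 * 160), 120, 160)
    d <- decode_heatmap(hm)
    df <- decode_heatmap(hm[, 160:1])
    expect_equal(df[["x"]], 159 - d[["x"]], tolerance = 1e-9)
    expect_equal(df[["y"]], d[["y"]], tolerance = 1e-9)
  }
})

test_that("negative responses are clamped and all-zero maps error", {
  hm <- matrix(-1, 30, 30)
  expect_error(decode_heatmap(hm), "undecodable")
  hm[15, 15] <- 2
  hm[15, 16] <- -2 # must not drag the centroid with negative weight
  expect_equal(decode_heatmap(hm), c(x = 14, y = 14))
})

test_that("the decoded scale maps heatmap grids to crop coordinates", {
  hm <- render_target_heatmap(c(40, 50), c(64, 80), sigma = 3,
                              scale = c(sx = 2, sy = 1.875))
  dec <- decode_heatmap(hm)
  expect_equal(dec, c(x = 80, y = 93.75), tolerance = 0.2)
})

test_that("regression predictions denormalize to crop coordinates", {
  m <- tiny_regression_model(seed = 4)
  # force known outputs by zeroing the final linear layer
  leaves <- nn_leaves(m$net)
  lin <- leaves[[length(leaves) - 1]]
  lin$par$w[] <- 0
  lin$par$b[] <- 0 # sigmoid(0) = 0.5 -> center of the crop
  crop <- matrix(runif(120 * 160), 120, 160)
  expect_equal(predict_keypoint(m, crop), c(x = 80, y = 60))
})

test_that("checkpoints restore predictions exactly", {
  m <- build_model(model_spec("mobilenetv2", "heatmap", width_mult = 0.25,
                              head_channels = c(8, 8, 4, 4, 4)), seed = 6)
  # give the zero-initialized response layer some signal to checkpoint
  leaves <- nn_leaves(m$net)
  last <- leaves[[length(leaves)]]
  set.seed(1)
  last$par$w[] <- rnorm(length(last$par$w), 0, 0.5)
  x <- array(runif(120 * 160 * 3), c(120, 160, 3, 1))
  # settle batch-norm running stats, then predict in eval mode
  invisible(nn_forward(m$net, x, training = TRUE))
  p1 <- predict_keypoint(m, x)
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(predict_keypoint(m2, x), p1, tolerance = 1e-12)
})
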