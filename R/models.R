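# Keypoint network variants: a backbone (VGG19 / ResNeXt50-32x4d /
# MobileNetV2) combined with either a coordinate-regression head or a
# heatmap head.
#
# Regression variant: the full backbone including its 1000-way ImageNet
# output, followed by a fully connected 1000 -> 2 layer (plus a sigmoid) so
# the output is the heel position normalized to the crop size, (x/160,
# y/120).
#
# Heatmap variant: the backbone's feature-extraction layers only, followed
# by five transposed-convolution layers (kernel 4, stride 2, pad 1, each
# with batch norm + ReLU) that upsample the stride-32 feature map back to
# roughly the input resolution, and a final 1x1 convolution down to a
# single channel. The keypoint is decoded from the response map as the
# intensity-weighted mean position in a 13x13 neighborhood around the
# maximum.

CROP_W <- 160L
CROP_H <- 120L

#' Specify a keypoint network
#'
#' @param backbone one of `"vgg19"`, `"resnext50"`, `"mobilenetv2"`.
#' @param head `"regression"` (normalized coordinates) or `"heatmap"`.
#' @param pretrained logical; reserved for initializing the backbone from
#'   external weights. The package trains from random initialization.
#' @param heatmap_sigma standard deviation (px, on the heatmap grid) of the
#'   Gaussian training target for the heatmap head.
#' @param width_mult MobileNetV2 width multiplier (its published alpha);
#'   ignored by the other backbones. 1.0 is the standard model.
#' @param head_channels channel schedule of the five transposed-conv layers
#'   of the heatmap head.
#' @param dropout dropout rate applied during training (in the backbone
#'   classifier for the regression head, before the heatmap head otherwise).
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(backbone = c("mobilenetv2", "vgg19", "resnext50"),
                       head = c("heatmap", "regression"),
                       pretrained = FALSE, heatmap_sigma = 3,
                       width_mult = 1.0,
                       head_channels = c(256L, 128L, 64L, 32L, 16L),
                       dropout = 0.5) {
  backbone <- match.arg(backbone)
  head <- match.arg(head)
  stopifnot(heatmap_sigma > 0, width_mult > 0, length(head_channels) == 5)
  structure(list(backbone = backbone, head = head, pretrained = pretrained,
                 heatmap_sigma = heatmap_sigma, width_mult = width_mult,
                 head_channels = as.integer(head_channels),
                 dropout = dropout,
                 input_size = c(w = CROP_W, h = CROP_H)),
            class = "model_spec")
}

heatmap_head <- function(in_ch, channels, dropout) {
  layers <- list(nn_dropout(dropout))
  for (ch in channels) {
    layers <- c(layers, list(nn_tbr(in_ch, ch, 4L, 2L, 1L, act = 1L)))
    in_ch <- ch
  }
  c(layers, list(nn_conv(in_ch, 1L, 1L)))
}

#' Build a keypoint network
#'
#' @param spec a [model_spec()].
#' @param init logical; allocate and initialize the weights. With
#'   `init = FALSE` only the architecture (shapes) is constructed, which is
#'   sufficient for [count_parameters()] and costs no memory.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `"gaitheel_model"`.
#' @export
build_model <- function(spec, init = TRUE, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  dp <- spec$dropout
  if (spec$head == "regression") {
    backbone <- switch(spec$backbone,
      vgg19 = nn_seq(vgg19_features(), vgg19_classifier(dp)),
      mobilenetv2 = {
        f <- mobilenetv2_features(spec$width_mult)
        nn_seq(f, mobilenetv2_classifier(attr(f, "out_channels"), dp))
      },
      resnext50 = nn_seq(resnext50_features(), resnext50_classifier()))
    net <- nn_seq(backbone, nn_linear(1000L, 2L), nn_sigmoid())
  } else {
    feat <- switch(spec$backbone,
      vgg19 = structure(vgg19_features(), out_channels = 512L),
      mobilenetv2 = mobilenetv2_features(spec$width_mult),
      resnext50 = resnext50_features())
    net <- nn_seq(c(list(feat),
                    heatmap_head(attr(feat, "out_channels"),
                                 spec$head_channels, dp)))
  }
  hw <- nn_out_hw(net, c(CROP_H, CROP_W))
  # grid-to-crop mapping: identity wherever the response grid covers the
  # crop (a convolutional decoder can realize constant shifts but not
  # position-dependent rescalings); linear scaling only when the grid is
  # smaller than the crop (e.g. the 96-row VGG19 grid)
  scale <- c(sx = if (hw[2] >= CROP_W) 1 else CROP_W / hw[2],
             sy = if (hw[1] >= CROP_H) 1 else CROP_H / hw[1])
  model <- list(spec = spec, net = net,
                out_hw = if (spec$head == "heatmap") hw else NULL,
                grid_to_input_scale = if (spec$head == "heatmap") scale
                                      else NULL)
  class(model) <- "gaitheel_model"
  if (init) {
    nn_init(net, seed)
    if (spec$head == "heatmap") {
      # start the response map at zero: the final 1x1 conv is zeroed so
      # early training shapes the response instead of first having to
      # shrink a random one
      leaves <- nn_leaves(net)
      last <- leaves[[length(leaves)]]
      last$par$w[] <- 0
      last$par$b[] <- 0
    }
  }
  model
}

#' Count trainable parameters of a model
#'
#' @param model a `"gaitheel_model"` (initialized or not).
#' @return integer total of trainable weights, biases and batch-norm affine
#'   parameters.
#' @export
count_parameters <- function(model) nn_count_parameters(model)

#' @export
print.gaitheel_model <- function(x, ...) {
  cat(sprintf("<gaitheel_model> %s-%s, %.1f M parameters\n",
              x$spec$backbone, x$spec$head, count_parameters(x) / 1e6))
  invisible(x)
}

#' Render a Gaussian target heatmap
#'
#' Isotropic Gaussian `exp(-((x-hx)^2 + (y-hy)^2) / (2 sigma^2))` with peak
#' value 1, evaluated on an integer pixel grid (0-based coordinates).
#'
#' @param heel keypoint (x, y) in heatmap-grid coordinates.
#' @param shape `c(h, w)` of the heatmap grid.
#' @param sigma Gaussian standard deviation in grid pixels.
#' @param scale grid-to-input scale factors `c(sx, sy)` recorded on the
#'   result (default 1, i.e. grid == input resolution).
#' @return a `"heatmap"` object: an h x w matrix with attribute
#'   `grid_to_input_scale`.
#' @export
render_target_heatmap <- function(heel, shape, sigma = 3,
                                  scale = c(sx = 1, sy = 1)) {
  if (sigma <= 0) stop("invalid parameter: sigma must be positive")
  h <- shape[1]; w <- shape[2]
  dx2 <- (seq_len(w) - 1 - heel[[1]])^2
  dy2 <- (seq_len(h) - 1 - heel[[2]])^2
  hm <- exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  structure(hm, grid_to_input_scale = scale, class = "heatmap")
}

#' Decode a heatmap to a keypoint
#'
#' Finds the global maximum (ties broken toward the smallest row-major
#' index), then takes the intensity-weighted mean position over the 13x13
#' window centered there (clipped at borders, negative responses clamped to
#' zero), and scales the result to input-crop coordinates using the
#' heatmap's `grid_to_input_scale`.
#'
#' @param hm matrix-like heatmap (optionally with a `grid_to_input_scale`
#'   attribute).
#' @param window odd neighborhood size (13 as published).
#' @return image point (x, y) in input-crop coordinates.
#' @export
decode_heatmap <- function(hm, window = 13L) {
  scale <- attr(hm, "grid_to_input_scale")
  if (is.null(scale)) scale <- c(sx = 1, sy = 1)
  m <- unclass(hm)
  attributes(m) <- list(dim = dim(hm))
  if (length(m) == 0) stop("undecodable heatmap: empty")
  h <- nrow(m); w <- ncol(m)
  # row-major tie break: scan by rows
  best <- which(t(m) == max(m), arr.ind = FALSE)[1]
  r0 <- (best - 1) %/% w + 1
  c0 <- (best - 1) %% w + 1
  half <- (window - 1L) %/% 2L
  rows <- max(1, r0 - half):min(h, r0 + half)
  cols <- max(1, c0 - half):min(w, c0 + half)
  win <- pmax(m[rows, cols, drop = FALSE], 0)
  s <- sum(win)
  if (s <= 0) stop("undecodable heatmap: no positive response")
  gx <- sum(sweep(win, 2, cols - 1, "*")) / s
  gy <- sum(win * (rows - 1)) / s
  image_point(gx * scale[["sx"]], gy * scale[["sy"]])
}

model_forward <- function(model, x, training = FALSE)
  nn_forward(model$net, x, training)

#' Predict the heel keypoint in a foot crop
#'
#' @param model a trained `"gaitheel_model"`.
#' @param crop a 120 x 160 matrix (grayscale, values in `[0, 1]`), a
#'   120 x 160 x C array, or a `"foot_crop"` object; or a 4-d batch array
#'   `(H, W, C, N)`.
#' @return image point (x, y) in crop coordinates, or an N x 2 matrix for a
#'   batch.
#' @export
predict_keypoint <- function(model, crop) {
  x <- crop_to_tensor(crop)
  y <- model_forward(model, x, training = FALSE)
  n <- dim(x)[4]
  if (model$spec$head == "regression") {
    out <- t(y) * rep(c(CROP_W, CROP_H), each = n)
  } else {
    out <- t(vapply(seq_len(n), function(i) {
      hm <- structure(y[, , 1, i],
                      grid_to_input_scale = model$grid_to_input_scale)
      decode_heatmap(hm)
    }, numeric(2)))
  }
  colnames(out) <- c("x", "y")
  if (n == 1) c(x = unname(out[1, 1]), y = unname(out[1, 2])) else out
}

# Accepts a matrix (H x W), an (H, W, C) array, a foot_crop, or an
# (H, W, C, N) batch; returns an (H, W, 3, N) tensor (gray replicated).
crop_to_tensor <- function(crop) {
  if (inherits(crop, "foot_crop")) crop <- crop$pixels
  if (is.matrix(crop)) dim(crop) <- c(dim(crop), 1L, 1L)
  else if (length(dim(crop)) == 3L) dim(crop) <- c(dim(crop), 1L)
  d <- dim(crop)
  if (d[1] != CROP_H || d[2] != CROP_W)
    stop("crop must be ", CROP_H, " rows x ", CROP_W, " columns")
  if (d[3] == 1L) crop <- crop[, , c(1L, 1L, 1L), , drop = FALSE]
  crop
}

#' Save / load model checkpoints
#'
#' Checkpoints hold the spec and all parameter and batch-norm state.
#' @param model a `"gaitheel_model"`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec = model$spec, state = nn_get_state(model$net)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$spec, init = TRUE)
  nn_set_state(model$net, ck$state)
  model
}
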