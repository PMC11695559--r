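# Backbone architectures, restated layer-by-layer from their published
# definitions so that parameter counts match the standard ImageNet models:
# VGG19, MobileNetV2 (with its width multiplier) and ResNeXt50-32x4d.

conv_bn_relu <- function(in_ch, out_ch, kernel = 3L, stride = 1L,
                         groups = 1L, cap = 6) {
  pad <- (kernel - 1L) %/% 2L
  nn_cbr(in_ch, out_ch, kernel, stride, pad, groups, act = 1L, cap = cap)
}

# ---- VGG19 -----------------------------------------------------------------

# Configuration "E": 16 conv layers + 3 fully connected = 19 weight layers.
vgg19_cfg <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, 256, NA,
               512, 512, 512, 512, NA, 512, 512, 512, 512, NA)

vgg19_features <- function() {
  layers <- list()
  in_ch <- 3L
  for (v in vgg19_cfg) {
    if (is.na(v)) {
      layers <- c(layers, list(nn_maxpool(2L, 2L)))
    } else {
      layers <- c(layers, list(nn_conv(in_ch, v, 3L, 1L, 1L), nn_relu()))
      in_ch <- as.integer(v)
    }
  }
  nn_seq(layers)
}

vgg19_classifier <- function(dropout = 0.5) {
  nn_seq(nn_avgpool(7L, 7L), nn_flatten(),
         nn_linear(512L * 7L * 7L, 4096L), nn_relu(), nn_dropout(dropout),
         nn_linear(4096L, 4096L), nn_relu(), nn_dropout(dropout),
         nn_linear(4096L, 1000L))
}

# ---- MobileNetV2 -----------------------------------------------------------

# Channel rounding used throughout MobileNetV2: round to the nearest multiple
# of `divisor`, never going below 90% of the original value.
make_divisible <- function(v, divisor = 8L, min_value = NULL) {
  if (is.null(min_value)) min_value <- divisor
  new_v <- max(min_value, (as.integer(v + divisor / 2) %/% divisor) * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

inverted_residual <- function(in_ch, out_ch, stride, expand) {
  hidden <- as.integer(round(in_ch * expand))
  layers <- list()
  if (expand != 1)
    layers <- c(layers, list(conv_bn_relu(in_ch, hidden, 1L)))
  layers <- c(layers,
              list(conv_bn_relu(hidden, hidden, 3L, stride, groups = hidden),
                   nn_cbr(hidden, out_ch, 1L, act = 0L)))
  block <- nn_seq(layers)
  if (stride == 1L && in_ch == out_ch) nn_residual(block) else block
}

# (expansion, channels, repeats, stride) rows of the published architecture.
mobilenetv2_setting <- list(
  c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
  c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))

mobilenetv2_features <- function(width_mult = 1.0) {
  in_ch <- make_divisible(32 * width_mult)
  last_ch <- make_divisible(1280 * max(1.0, width_mult))
  layers <- list(conv_bn_relu(3L, in_ch, 3L, 2L))
  for (row in mobilenetv2_setting) {
    t <- row[1]; c <- make_divisible(row[2] * width_mult)
    n <- row[3]; s <- row[4]
    for (i in seq_len(n)) {
      stride <- if (i == 1L) as.integer(s) else 1L
      layers <- c(layers, list(inverted_residual(in_ch, c, stride, t)))
      in_ch <- c
    }
  }
  layers <- c(layers, list(conv_bn_relu(in_ch, last_ch, 1L)))
  structure(nn_seq(layers), out_channels = last_ch)
}

mobilenetv2_classifier <- function(last_ch, dropout = 0.5) {
  nn_seq(nn_avgpool(1L, 1L), nn_flatten(), nn_dropout(dropout),
         nn_linear(last_ch, 1000L))
}

# ---- ResNeXt50 (32x4d) -----------------------------------------------------

resnext_bottleneck <- function(in_ch, planes, stride, groups = 32L,
                               base_width = 4L) {
  width <- as.integer(planes * base_width / 64) * groups
  out_ch <- planes * 4L
  main <- nn_seq(
    nn_conv(in_ch, width, 1L, bias = FALSE), nn_bn(width), nn_relu(),
    nn_conv(width, width, 3L, stride, 1L, groups, bias = FALSE),
    nn_bn(width), nn_relu(),
    nn_conv(width, out_ch, 1L, bias = FALSE), nn_bn(out_ch))
  shortcut <- NULL
  if (stride != 1L || in_ch != out_ch)
    shortcut <- nn_seq(nn_conv(in_ch, out_ch, 1L, stride, bias = FALSE),
                       nn_bn(out_ch))
  nn_residual(main, shortcut, post_relu = TRUE)
}

resnext50_features <- function() {
  layers <- list(nn_conv(3L, 64L, 7L, 2L, 3L, bias = FALSE), nn_bn(64L),
                 nn_relu(), nn_maxpool(3L, 2L, 1L))
  in_ch <- 64L
  blocks <- c(3L, 4L, 6L, 3L)
  planes <- c(64L, 128L, 256L, 512L)
  strides <- c(1L, 2L, 2L, 2L)
  for (k in seq_along(blocks)) {
    for (i in seq_len(blocks[k])) {
      stride <- if (i == 1L) strides[k] else 1L
      layers <- c(layers,
                  list(resnext_bottleneck(in_ch, planes[k], stride)))
      in_ch <- planes[k] * 4L
    }
  }
  structure(nn_seq(layers), out_channels = in_ch)
}

resnext50_classifier <- function() {
  nn_seq(nn_avgpool(1L, 1L), nn_flatten(), nn_linear(2048L, 1000L))
}

# ---- shape arithmetic ------------------------------------------------------

# Spatial output size (H, W) of a network for a given input size, from the
# layers' stride/padding arithmetic (no forward pass needed).
nn_out_hw <- function(layer, hw) {
  switch(layer$type,
    seq = {
      for (l in layer$layers) hw <- nn_out_hw(l, hw)
      hw
    },
    residual = nn_out_hw(layer$main, hw),
    conv = , cbr = (hw + 2L * layer$cfg$p - layer$cfg$k) %/% layer$cfg$s + 1L,
    convt = , tbr = (hw - 1L) * layer$cfg$s + layer$cfg$k - 2L * layer$cfg$p,
    maxpool = (hw + 2L * layer$cfg$p - layer$cfg$k) %/% layer$cfg$s + 1L,
    avgpool = c(layer$cfg$oh, layer$cfg$ow),
    hw)
}
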