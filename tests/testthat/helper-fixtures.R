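# Shared fixtures, built in code.

# Similarity (scale + rotation + translation) image->floor homography.
# Under a similarity, image heel-to-heel distance is proportional to world
# distance, so planted strike frames stay exact distance maxima.
sim_homography <- function(scale = 0.5, angle = 0.1, tx = 12, ty = -4) {
  ca <- cos(angle) * scale
  sa <- sin(angle) * scale
  structure(rbind(c(ca, -sa, tx), c(sa, ca, ty), c(0, 0, 1)),
            class = "homography")
}

# Mildly projective homography for estimation tests.
proj_homography <- function() {
  structure(matrix(c(0.5, 0.02, 10,
                     -0.01, 0.48, 5,
                     1e-4, 2e-5, 1), 3, 3, byrow = TRUE),
            class = "homography")
}

# A deterministic labelled sample with its source frame attached.
fixture_sample <- function(seed = 5L) {
  synth_labelled_samples(1, rng_seed = seed, keep_frames = TRUE)[[1]]
}

# Tiny coordinate-regression convnet wrapped as a gaitheel model, for
# training-loop tests where a full backbone would be overkill.
tiny_regression_model <- function(seed = 1L) {
  net <- nn_seq(
    nn_conv(3L, 8L, 5L, stride = 4L, pad = 2L), nn_bn(8L), nn_relu(),
    nn_maxpool(2L, 2L),
    nn_conv(8L, 16L, 3L, stride = 2L, pad = 1L), nn_bn(16L), nn_relu(),
    nn_avgpool(4L, 5L), nn_flatten(),
    nn_linear(16L * 4L * 5L, 2L), nn_sigmoid())
  model <- list(spec = list(backbone = "tiny", head = "regression",
                            heatmap_sigma = 3, dropout = 0),
                net = net, out_hw = NULL, grid_to_input_scale = NULL)
  class(model) <- "gaitheel_model"
  nn_init(net, seed)
  model
}
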