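# The package's desk-scale end-to-end study: train a MobileNetV2 heatmap
# model from random initialization on synthetic foot crops and measure
# held-out keypoint error, in pixels and floor centimeters. Problem sizes
# (800 training crops of distinct scenes, width multiplier 0.25, narrow
# transposed-conv head, Gaussian target sigma 16, lr 0.25) are chosen for
# a single CPU and a short from-scratch run; the methods vignette
# discusses each choice.

#' Desk-scale heel-localization experiment
#'
#' Generates a synthetic labelled corpus (one crop per rendered scene),
#' splits it by subject, trains a scaled-down MobileNetV2 heatmap model
#' under the standard protocol (SGD, momentum 0.9, weight decay 1e-4, lr
#' decay 0.1 after 10 epochs, early stopping patience 4) and evaluates
#' keypoint errors on crops of held-out subjects.
#'
#' @param seed master seed; corpus, initialization and shuffling seeds are
#'   derived from it.
#' @param n_train,n_val,n_test crops per split (split by subject, 4 crops
#'   per subject).
#' @param epochs maximum training epochs.
#' @param width_mult MobileNetV2 width multiplier of the trained model.
#' @param head_channels transposed-conv head schedule.
#' @param lr,batch_size optimizer settings (validation-tuned defaults).
#' @param sigma Gaussian target width (heatmap grid px).
#' @param verbose print per-epoch progress.
#' @return list: `fit` (from [train_model()]), `test_errors` (from
#'   [keypoint_errors()]), `config` (the [train_config()] used), `spec`,
#'   `n_train`, and `floor_summary` (a [summarize_errors()] of floor-axis
#'   errors in cm under a nominal 0.25 cm/px side-view calibration).
#' @export
desk_scale_experiment <- function(seed = 1L, n_train = 800L, n_val = 100L,
                                  n_test = 100L, epochs = 12L,
                                  width_mult = 0.25,
                                  head_channels = c(32L, 16L, 8L, 8L, 4L),
                                  lr = 0.25, batch_size = 8L, sigma = 16,
                                  verbose = FALSE) {
  seed <- as.integer(seed) %% 100000L
  per_subject <- 4L
  n <- n_train + n_val + n_test
  stopifnot(n %% per_subject == 0, n_train %% per_subject == 0,
            n_val %% per_subject == 0, n_test %% per_subject == 0)
  samples <- synth_labelled_samples(n, rng_seed = seed + 1L,
                                    samples_per_subject = per_subject)
  split <- split_by_subject(
    samples, split_spec(n_train %/% per_subject, n_val %/% per_subject,
                        n_test %/% per_subject, seed = seed + 2L))

  spec <- model_spec("mobilenetv2", "heatmap", width_mult = width_mult,
                     head_channels = head_channels, heatmap_sigma = sigma,
                     dropout = 0)
  model <- build_model(spec, seed = seed + 3L)
  cfg <- train_config(epochs = epochs, batch_size = batch_size, lr = lr,
                      patience = 4L, seed = seed + 4L)
  fit <- train_model(model, split$train, split$val, cfg, verbose = verbose)
  test_errors <- keypoint_errors(fit$model, split$test)

  # floor-axis view of the same errors under a nominal side-view
  # calibration of 0.25 cm/px, crop origin at the frame origin
  h <- structure(diag(c(0.25, 0.25, 1)), class = "homography")
  cm <- vapply(seq_len(nrow(test_errors)), function(i)
    floor_axis_error(c(test_errors$pred_x[i], test_errors$pred_y[i]),
                     c(test_errors$label_x[i], test_errors$label_y[i]),
                     image_point(0, 0), h, "side"), numeric(1))
  list(fit = fit, test_errors = test_errors, config = cfg, spec = spec,
       n_train = length(split$train), floor_summary = summarize_errors(cm))
}
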