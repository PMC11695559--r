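# Training protocol for the keypoint networks: SGD with momentum 0.9 and
# weight decay 1e-4, mean-square error on the point prediction (normalized
# coordinates for the regression head, per-pixel on the response map for
# the heatmap head), learning rate decayed by 0.1 after 10 epochs, early
# stopping with patience 4, best-validation weights restored.

#' Training configuration
#'
#' @param epochs maximum epochs (20 as published).
#' @param batch_size minibatch size (tuned per model in 8..12).
#' @param lr initial learning rate (tuned per model in 1e-3..1e-2).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param lr_decay_factor,lr_decay_epoch learning rate is multiplied by the
#'   factor after `lr_decay_epoch` epochs (i.e. from epoch
#'   `lr_decay_epoch + 1` on).
#' @param patience early stopping: stop when the validation loss has not
#'   decreased below its best for this many consecutive epochs.
#' @param seed seed controlling initialization, shuffling and dropout.
#' @export
train_config <- function(epochs = 20L, batch_size = 8L, lr = 1e-3,
                         momentum = 0.9, weight_decay = 1e-4,
                         lr_decay_factor = 0.1, lr_decay_epoch = 10L,
                         patience = 4L, seed = 1L) {
  stopifnot(epochs > 0, batch_size > 0, lr > 0, patience > 0,
            patience < epochs)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 momentum = momentum, weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_epoch = as.integer(lr_decay_epoch),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

#' Mean-square error loss
#'
#' Mean of squared differences over all components: normalized coordinates
#' for point predictions, per-pixel values for heatmaps.
#' @param predicted,target numeric vectors, matrices or arrays of identical
#'   shape.
#' @return scalar loss.
#' @export
loss_mse <- function(predicted, target) {
  if (!identical(dim(predicted), dim(target)) ||
      length(predicted) != length(target))
    stop("shape mismatch between prediction and target")
  mean((predicted - target)^2)
}

# Stack samples into the input tensor and the training target for the
# given head.
samples_to_batch <- function(samples, model) {
  n <- length(samples)
  x <- array(0, c(CROP_H, CROP_W, 3L, n))
  for (i in seq_len(n)) x[, , , i] <- crop_to_tensor(samples[[i]]$crop)
  if (model$spec$head == "regression") {
    tgt <- vapply(samples, function(s)
      c(s$heel[["x"]] / CROP_W, s$heel[["y"]] / CROP_H), numeric(2))
    dim(tgt) <- c(2L, n)
  } else {
    hw <- model$out_hw
    sc <- model$grid_to_input_scale
    tgt <- array(0, c(hw[1], hw[2], 1L, n))
    for (i in seq_len(n)) {
      hm <- render_target_heatmap(
        c(samples[[i]]$heel[["x"]] / sc[["sx"]],
          samples[[i]]$heel[["y"]] / sc[["sy"]]),
        hw, model$spec$heatmap_sigma)
      tgt[, , 1L, i] <- hm
    }
  }
  list(x = x, target = tgt)
}

dataset_loss <- function(model, samples, batch_size = 16L) {
  tot <- 0
  n <- 0
  for (idx in split(seq_along(samples),
                    ceiling(seq_along(samples) / batch_size))) {
    b <- samples_to_batch(samples[idx], model)
    pred <- model_forward(model, b$x, training = FALSE)
    tot <- tot + loss_mse(pred, b$target) * length(b$target)
    n <- n + length(b$target)
  }
  tot / n
}

#' Train a keypoint network
#'
#' One view (side or frontal) per model; never mix views. Fully
#' reproducible under a fixed seed.
#'
#' @param model a `"gaitheel_model"` from [build_model()] (its weights are
#'   updated in place).
#' @param train_set,val_set lists of [labelled_sample()] objects.
#' @param cfg a [train_config()].
#' @param val_metric optional function `(model, val_set, epoch) -> scalar`
#'   replacing the default validation loss (used to study the stopping
#'   rule).
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-validation weights restored), `history`
#'   (data.frame: epoch, train_loss, val_loss, lr), `stopped_epoch`,
#'   `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set, cfg = train_config(),
                        val_metric = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(train_set) == 0 || length(val_set) == 0)
    stop("empty dataset")
  view <- unique(vapply(train_set, function(s) s$crop$view, character(1)))
  if (length(view) > 1)
    stop("train_set mixes views (", paste(view, collapse = ", "),
         "); train separate models per view")
  set.seed(cfg$seed)
  net <- model$net
  opt_state <- NULL
  best <- Inf
  best_epoch <- 0L
  best_state <- NULL
  wait <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  stopped <- cfg$epochs
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cfg$lr *
      if (epoch > cfg$lr_decay_epoch) cfg$lr_decay_factor else 1
    ord <- base::sample(length(train_set))
    ep_loss <- 0
    ep_n <- 0
    for (idx in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      b <- samples_to_batch(train_set[idx], model)
      nn_zero_grad(net)
      pred <- nn_forward(net, b$x, training = TRUE)
      l <- loss_mse(pred, b$target)
      if (!is.finite(l))
        stop("divergence: non-finite training loss at epoch ", epoch)
      g <- 2 * (pred - b$target) / length(b$target)
      nn_backward(net, g)
      opt_state <- sgd_step(net, opt_state, lr, cfg$momentum,
                            cfg$weight_decay)
      ep_loss <- ep_loss + l * length(idx)
      ep_n <- ep_n + length(idx)
    }
    train_loss <- ep_loss / ep_n
    val_loss <- if (is.null(val_metric)) dataset_loss(model, val_set)
                else val_metric(model, val_set, epoch)
    if (!is.finite(val_loss))
      stop("divergence: non-finite validation loss at epoch ", epoch)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss, lr = lr))
    if (verbose)
      message(sprintf("epoch %2d  lr %.4g  train %.5g  val %.5g",
                      epoch, lr, train_loss, val_loss))
    if (val_loss < best) {
      best <- val_loss
      best_epoch <- epoch
      best_state <- nn_get_state(net)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) {
        stopped <- epoch
        break
      }
    }
  }
  if (!is.null(best_state)) nn_set_state(net, best_state)
  list(model = model, history = hist, stopped_epoch = as.integer(stopped),
       best_epoch = best_epoch)
}

#' Keypoint error of a model on labelled samples
#'
#' @param model trained model.
#' @param samples labelled samples.
#' @return data.frame with per-sample predicted and labelled crop
#'   coordinates and the Euclidean pixel error.
#' @export
keypoint_errors <- function(model, samples) {
  out <- lapply(split(seq_along(samples),
                      ceiling(seq_along(samples) / 16)), function(idx) {
    b <- samples_to_batch(samples[idx], model)
    pred <- predict_keypoint(model, b$x)
    if (is.null(dim(pred))) pred <- matrix(pred, 1, 2)
    lab <- t(vapply(samples[idx], function(s)
      c(s$heel[["x"]], s$heel[["y"]]), numeric(2)))
    data.frame(pred_x = pred[, 1], pred_y = pred[, 2],
               label_x = lab[, 1], label_y = lab[, 2],
               error_px = sqrt(rowSums((pred - lab)^2)))
  })
  do.call(rbind, out)
}
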