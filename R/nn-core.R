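# Minimal CNN engine used by the keypoint networks.
#
# Tensors are plain R arrays, dim c(H, W, C, N); flattened / fully connected
# activations are matrices (features x N). Layers are environments holding
# parameter arrays, gradients and a forward cache; containers (`nn_seq`,
# `nn_residual`) compose them. Convolution, transposed convolution and max
# pooling run through the compiled im2col/GEMM kernels in src/.

new_layer <- function(type, cfg = list(), shapes = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$cfg <- cfg
  e$shapes <- shapes
  e$par <- NULL
  e$grad <- NULL
  e$buf <- list()
  e$cache <- NULL
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

nn_conv <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                    groups = 1L, bias = TRUE) {
  stopifnot(in_ch %% groups == 0, out_ch %% groups == 0)
  shapes <- list(w = c(kernel, kernel, in_ch %/% groups, out_ch))
  if (bias) shapes$b <- out_ch
  new_layer("conv", list(k = as.integer(kernel), s = as.integer(stride),
                         p = as.integer(pad), g = as.integer(groups),
                         bias = bias, in_ch = in_ch, out_ch = out_ch), shapes)
}

nn_convt <- function(in_ch, out_ch, kernel, stride = 2L, pad = 1L,
                     bias = TRUE, groups = 1L) {
  shapes <- list(w = c(kernel, kernel, out_ch %/% groups, in_ch))
  if (bias) shapes$b <- out_ch
  new_layer("convt", list(k = as.integer(kernel), s = as.integer(stride),
                          p = as.integer(pad), g = as.integer(groups),
                          bias = bias, in_ch = in_ch, out_ch = out_ch), shapes)
}

nn_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_layer("bn", list(ch = ch, eps = eps, momentum = momentum),
            list(gamma = ch, beta = ch))
}

# Fused conv -> batch norm -> activation (act 0 = none, 1 = capped ReLU);
# one compiled call per direction instead of three layers.
nn_cbr <- function(in_ch, out_ch, kernel, stride = 1L, pad = 0L,
                   groups = 1L, act = 1L, cap = 6, eps = 1e-5,
                   momentum = 0.1) {
  new_layer("cbr",
            list(k = as.integer(kernel), s = as.integer(stride),
                 p = as.integer(pad), g = as.integer(groups),
                 act = as.integer(act), cap = cap, ch = out_ch,
                 eps = eps, momentum = momentum,
                 in_ch = in_ch, out_ch = out_ch),
            list(w = c(kernel, kernel, in_ch %/% groups, out_ch),
                 gamma = out_ch, beta = out_ch))
}

# Fused transposed conv -> batch norm -> activation.
nn_tbr <- function(in_ch, out_ch, kernel = 4L, stride = 2L, pad = 1L,
                   act = 1L, cap = Inf, eps = 1e-5, momentum = 0.1) {
  new_layer("tbr",
            list(k = as.integer(kernel), s = as.integer(stride),
                 p = as.integer(pad), g = 1L, act = as.integer(act),
                 cap = cap, ch = out_ch, eps = eps, momentum = momentum,
                 in_ch = in_ch, out_ch = out_ch),
            list(w = c(kernel, kernel, out_ch, in_ch),
                 gamma = out_ch, beta = out_ch))
}

nn_relu <- function(cap = Inf) new_layer("relu", list(cap = cap))
nn_sigmoid <- function() new_layer("sigmoid")
nn_maxpool <- function(kernel = 2L, stride = 2L, pad = 0L)
  new_layer("maxpool", list(k = as.integer(kernel), s = as.integer(stride),
                            p = as.integer(pad)))
nn_avgpool <- function(out_h = 1L, out_w = 1L)
  new_layer("avgpool", list(oh = as.integer(out_h), ow = as.integer(out_w)))
nn_flatten <- function() new_layer("flatten")
nn_dropout <- function(p = 0.5) new_layer("dropout", list(p = p))

nn_linear <- function(in_features, out_features, bias = TRUE) {
  shapes <- list(w = c(out_features, in_features))
  if (bias) shapes$b <- out_features
  new_layer("linear", list(in_f = in_features, out_f = out_features,
                           bias = bias), shapes)
}

nn_seq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_layer")) layers <- layers[[1]]
  e <- new_layer("seq")
  e$layers <- layers
  e
}

nn_residual <- function(main, shortcut = NULL, post_relu = FALSE) {
  e <- new_layer("residual", list(post_relu = post_relu))
  e$main <- main
  e$shortcut <- shortcut
  e
}

# ---- traversal -------------------------------------------------------------

nn_children <- function(layer) {
  switch(layer$type,
    seq = layer$layers,
    residual = Filter(Negate(is.null), list(layer$main, layer$shortcut)),
    list())
}

nn_leaves <- function(layer) {
  kids <- nn_children(layer)
  if (length(kids) == 0L) return(list(layer))
  do.call(c, lapply(kids, nn_leaves))
}

#' Count trainable parameters of a network
#'
#' Sums the sizes of every weight, bias and batch-norm affine parameter.
#' Works on uninitialized networks (counts come from declared shapes).
#'
#' @param net a network built with the `nn_*` constructors or [build_model()].
#' @return integer parameter count.
#' @export
nn_count_parameters <- function(net) {
  if (inherits(net, "gaitheel_model")) net <- net$net
  s <- 0
  for (l in nn_leaves(net))
    for (sh in l$shapes) s <- s + prod(sh)
  as.integer(s)
}

nn_init <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (l in nn_leaves(net)) {
    l$par <- list(); l$grad <- list()
    for (nm in names(l$shapes)) {
      sh <- l$shapes[[nm]]
      n <- prod(sh)
      v <- switch(l$type,
        conv = , convt = , cbr = , tbr = {
          if (nm == "b" || nm == "beta") numeric(n)
          else if (nm == "gamma") rep(1, n)
          else {
            fan_in <- prod(sh[-length(sh)])
            stats::rnorm(n, 0, sqrt(2 / fan_in))
          }
        },
        bn = if (nm == "gamma") rep(1, n) else numeric(n),
        linear = {
          if (nm == "b") numeric(n)
          else stats::runif(n, -1, 1) / sqrt(l$cfg$in_f)
        },
        numeric(n))
      l$par[[nm]] <- if (length(sh) > 1L) array(v, sh) else v
      l$grad[[nm]] <- if (length(sh) > 1L) array(0, sh) else numeric(n)
    }
    if (l$type %in% c("bn", "cbr", "tbr"))
      l$buf <- list(rm = numeric(l$cfg$ch), rv = rep(1, l$cfg$ch))
  }
  invisible(net)
}

nn_zero_grad <- function(net) {
  for (l in nn_leaves(net))
    for (nm in names(l$grad)) l$grad[[nm]][] <- 0
  invisible(net)
}

nn_get_state <- function(net)
  lapply(nn_leaves(net), function(l) list(par = l$par, buf = l$buf))

nn_set_state <- function(net, state) {
  leaves <- nn_leaves(net)
  stopifnot(length(leaves) == length(state))
  for (i in seq_along(leaves)) {
    leaves[[i]]$par <- state[[i]]$par
    leaves[[i]]$buf <- state[[i]]$buf
  }
  invisible(net)
}

# ---- forward / backward ----------------------------------------------------

nn_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    seq = {
      for (l in layer$layers) x <- nn_forward(l, x, training)
      x
    },
    residual = {
      m <- nn_forward(layer$main, x, training)
      s <- if (is.null(layer$shortcut)) x
           else nn_forward(layer$shortcut, x, training)
      y <- m + s
      if (layer$cfg$post_relu) {
        layer$cache <- y > 0
        y <- y * layer$cache
      }
      y
    },
    conv = {
      d <- dim(x)
      layer$cache <- list(x = x, d = d)
      conv2d_fwd_cpp(x, layer$par$w, if (layer$cfg$bias) layer$par$b else 0,
                     as.integer(d), layer$cfg$k, layer$cfg$k, layer$cfg$s,
                     layer$cfg$s, layer$cfg$p, layer$cfg$p, layer$cfg$g,
                     layer$cfg$bias)
    },
    convt = {
      d <- dim(x)
      layer$cache <- list(x = x, d = d)
      convt2d_fwd_cpp(x, layer$par$w, if (layer$cfg$bias) layer$par$b else 0,
                      as.integer(d), layer$cfg$k, layer$cfg$k, layer$cfg$s,
                      layer$cfg$s, layer$cfg$p, layer$cfg$p, layer$cfg$g,
                      layer$cfg$bias)
    },
    bn = {
      r <- bn_fwd_cpp(x, as.integer(dim(x)), layer$par$gamma,
                      layer$par$beta, layer$buf$rm, layer$buf$rv,
                      layer$cfg$eps, layer$cfg$momentum, training)
      if (training) {
        layer$buf$rm <- r$rm
        layer$buf$rv <- r$rv
      }
      layer$cache <- list(xhat = r$xhat, invstd = r$invstd, d = dim(x),
                          training = training)
      r$y
    },
    cbr = , tbr = {
      fwd <- if (layer$type == "cbr") fused_cbr_fwd_cpp else fused_tbr_fwd_cpp
      r <- fwd(x, layer$par$w, as.integer(dim(x)), layer$cfg$k, layer$cfg$s,
               layer$cfg$p, layer$cfg$g, layer$par$gamma, layer$par$beta,
               layer$buf$rm, layer$buf$rv, layer$cfg$eps,
               layer$cfg$momentum, training, layer$cfg$act, layer$cfg$cap)
      if (training) {
        layer$buf$rm <- r$rm
        layer$buf$rv <- r$rv
      }
      layer$cache <- list(x = x, d = dim(x), xhat = r$xhat,
                          invstd = r$invstd, y = r$y, training = training)
      r$y
    },
    relu = {
      layer$cache <- x
      y <- relu_fwd_cpp(x, layer$cfg$cap)
      dim(y) <- dim(x)
      y
    },
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      layer$cache <- y
      y
    },
    maxpool = {
      d <- dim(x)
      r <- maxpool2d_fwd_cpp(x, as.integer(d), layer$cfg$k, layer$cfg$s,
                             layer$cfg$p)
      layer$cache <- list(idx = r$idx, d = d)
      r$y
    },
    avgpool = avgpool_forward(layer, x),
    flatten = {
      d <- dim(x)
      layer$cache <- d
      dim(x) <- c(prod(d[1:3]), d[4])
      x
    },
    dropout = {
      if (!training || layer$cfg$p <= 0) {
        layer$cache <- NULL
        x
      } else {
        mask <- (stats::runif(length(x)) >= layer$cfg$p) / (1 - layer$cfg$p)
        dim(mask) <- dim(x)
        layer$cache <- mask
        x * mask
      }
    },
    linear = {
      layer$cache <- x
      y <- layer$par$w %*% x
      if (layer$cfg$bias) y <- y + layer$par$b
      y
    },
    stop("unknown layer type: ", layer$type))
}

nn_backward <- function(layer, g) {
  switch(layer$type,
    seq = {
      for (l in rev(layer$layers)) g <- nn_backward(l, g)
      g
    },
    residual = {
      if (layer$cfg$post_relu) g <- g * layer$cache
      gm <- nn_backward(layer$main, g)
      gs <- if (is.null(layer$shortcut)) g
            else nn_backward(layer$shortcut, g)
      gm + gs
    },
    conv = {
      r <- conv2d_bwd_cpp(layer$cache$x, layer$par$w, g,
                          as.integer(layer$cache$d), layer$cfg$k, layer$cfg$k,
                          layer$cfg$s, layer$cfg$s, layer$cfg$p, layer$cfg$p,
                          layer$cfg$g, layer$cfg$bias)
      layer$grad$w <- layer$grad$w + r$gw
      if (layer$cfg$bias) layer$grad$b <- layer$grad$b + r$gb
      r$gx
    },
    convt = {
      r <- convt2d_bwd_cpp(layer$cache$x, layer$par$w, g,
                           as.integer(layer$cache$d), layer$cfg$k, layer$cfg$k,
                           layer$cfg$s, layer$cfg$s, layer$cfg$p, layer$cfg$p,
                           layer$cfg$g, layer$cfg$bias)
      layer$grad$w <- layer$grad$w + r$gw
      if (layer$cfg$bias) layer$grad$b <- layer$grad$b + r$gb
      r$gx
    },
    bn = {
      cc <- layer$cache
      r <- bn_bwd_cpp(g, cc$xhat, as.integer(cc$d), cc$invstd,
                      layer$par$gamma, cc$training)
      layer$grad$gamma <- layer$grad$gamma + r$ggamma
      layer$grad$beta <- layer$grad$beta + r$gbeta
      r$gx
    },
    cbr = , tbr = {
      cc <- layer$cache
      bwd <- if (layer$type == "cbr") fused_cbr_bwd_cpp else fused_tbr_bwd_cpp
      r <- bwd(g, cc$y, cc$xhat, cc$invstd, layer$par$gamma, cc$x,
               layer$par$w, as.integer(cc$d), layer$cfg$k, layer$cfg$s,
               layer$cfg$p, layer$cfg$g, cc$training, layer$cfg$act,
               layer$cfg$cap)
      layer$grad$w <- layer$grad$w + r$gw
      layer$grad$gamma <- layer$grad$gamma + r$ggamma
      layer$grad$beta <- layer$grad$beta + r$gbeta
      r$gx
    },
    relu = {
      gx <- relu_bwd_cpp(g, layer$cache, layer$cfg$cap)
      dim(gx) <- dim(g)
      gx
    },
    sigmoid = g * layer$cache * (1 - layer$cache),
    maxpool = maxpool2d_bwd_cpp(g, layer$cache$idx,
                                as.integer(layer$cache$d)),
    avgpool = avgpool_backward(layer, g),
    flatten = {
      dim(g) <- layer$cache
      g
    },
    dropout = if (is.null(layer$cache)) g else g * layer$cache,
    linear = {
      x <- layer$cache
      layer$grad$w <- layer$grad$w + g %*% t(x)
      if (layer$cfg$bias) layer$grad$b <- layer$grad$b + rowSums(g)
      crossprod(layer$par$w, g)
    },
    stop("unknown layer type: ", layer$type))
}

# Adaptive average pooling: window edges at floor(i*H/oH) .. ceil((i+1)*H/oH),
# matching the usual adaptive-pooling convention.
avgpool_windows <- function(n_in, n_out) {
  lapply(seq_len(n_out), function(i) {
    lo <- floor((i - 1) * n_in / n_out) + 1
    hi <- ceiling(i * n_in / n_out)
    lo:hi
  })
}

avgpool_forward <- function(layer, x) {
  d <- dim(x)
  oh <- layer$cfg$oh; ow <- layer$cfg$ow
  wh <- avgpool_windows(d[1], oh)
  ww <- avgpool_windows(d[2], ow)
  y <- array(0, c(oh, ow, d[3], d[4]))
  for (i in seq_len(oh))
    for (j in seq_len(ow)) {
      xw <- x[wh[[i]], ww[[j]], , , drop = FALSE]
      dm <- dim(xw)
      y[i, j, , ] <- colMeans(matrix(xw, nrow = dm[1] * dm[2]))
    }
  layer$cache <- list(d = d, wh = wh, ww = ww)
  y
}

avgpool_backward <- function(layer, g) {
  cc <- layer$cache
  d <- cc$d
  gx <- array(0, d)
  for (i in seq_along(cc$wh))
    for (j in seq_along(cc$ww)) {
      hs <- cc$wh[[i]]; ws <- cc$ww[[j]]
      share <- g[i, j, , ] / (length(hs) * length(ws))
      add <- aperm(array(share, c(d[3], d[4], length(hs), length(ws))),
                   c(3, 4, 1, 2))
      gx[hs, ws, , ] <- gx[hs, ws, , ] + add
    }
  gx
}

# SGD with classical momentum and decoupled-from-nothing L2 weight decay,
# i.e. grad + wd * par feeds the velocity, as in the standard implementation.
sgd_step <- function(net, state, lr, momentum = 0.9, weight_decay = 1e-4) {
  leaves <- nn_leaves(net)
  if (is.null(state)) {
    state <- lapply(leaves, function(l) lapply(l$par, function(p) p * 0))
  }
  for (i in seq_along(leaves)) {
    l <- leaves[[i]]
    for (nm in names(l$par)) {
      g <- l$grad[[nm]]
      if (weight_decay > 0 && l$type != "bn" &&
          !(nm %in% c("gamma", "beta")))
        g <- g + weight_decay * l$par[[nm]]
      v <- momentum * state[[i]][[nm]] + g
      state[[i]][[nm]] <- v
      l$par[[nm]] <- l$par[[nm]] - lr * v
    }
  }
  state
}
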