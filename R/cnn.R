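# Compact convolutional network: 256x256x1 input, a fixed 4x4
# average-pooling stem (feature images are smooth at full resolution, so
# pooling to 64x64 costs nothing measurable and keeps CPU training cheap),
# four 3x3 'same' conv blocks (16/32/64/128 channels, ReLU, 2x2 max pool),
# global average pooling, one 128-unit dense layer with dropout 0.5, and a
# softmax output.

CNN_WIDTHS <- c(16L, 32L, 64L, 128L)
CNN_HIDDEN <- 128L
CNN_STEM <- 4L
CNN_INPUT <- 256L
CNN_DROPOUT <- 0.5

# He-normal initialization, deterministic given seed.
init_cnn_params <- function(n_classes, seed) {
  with_seed(seed, {
    p <- list(conv = vector("list", length(CNN_WIDTHS)))
    c_in <- 1L
    for (i in seq_along(CNN_WIDTHS)) {
      c_out <- CNN_WIDTHS[i]
      fan_in <- 9L * c_in
      p$conv[[i]] <- list(
        W = matrix(rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)), c_out, fan_in),
        b = rep(0, c_out))
      c_in <- c_out
    }
    g <- CNN_WIDTHS[length(CNN_WIDTHS)]
    p$fc1 <- list(W = matrix(rnorm(CNN_HIDDEN * g, sd = sqrt(2 / g)),
                             CNN_HIDDEN, g),
                  b = rep(0, CNN_HIDDEN))
    p$fc2 <- list(W = matrix(rnorm(n_classes * CNN_HIDDEN,
                                   sd = sqrt(2 / CNN_HIDDEN)),
                             n_classes, CNN_HIDDEN),
                  b = rep(0, n_classes))
    p
  })
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# Forward pass on one 256x256 image. dropout_mask: NULL (inference) or a
# precomputed inverted-dropout mask for the hidden dense layer.
cnn_forward <- function(params, image, dropout_mask = NULL) {
  if (is.null(dim(image)) || nrow(image) != CNN_INPUT ||
      ncol(image) != CNN_INPUT)
    stop("compact CNN expects a ", CNN_INPUT, "x", CNN_INPUT,
         " single-channel image")
  x <- cnn_avgpool(unclass(image)[,], CNN_STEM)
  a <- array(x, c(dim(x), 1L))
  cache <- list(blocks = vector("list", length(params$conv)))
  for (i in seq_along(params$conv)) {
    z <- cnn_conv2d_forward(a, params$conv[[i]]$W, params$conv[[i]]$b, 3L)
    r <- z * (z > 0)
    pl <- cnn_maxpool2_forward(r)
    cache$blocks[[i]] <- list(input = a, pre_relu = z, idx = pl$idx,
                              in_dim = dim(r))
    a <- pl$y
  }
  g <- apply(a, 3L, mean)
  cache$gap_dim <- dim(a)
  cache$g <- g
  h_lin <- drop(params$fc1$W %*% g) + params$fc1$b
  h <- pmax(h_lin, 0)
  if (!is.null(dropout_mask)) h <- h * dropout_mask
  cache$h_lin <- h_lin
  cache$h <- h
  cache$dropout_mask <- dropout_mask
  probs <- softmax(drop(params$fc2$W %*% h) + params$fc2$b)
  list(probs = probs, cache = cache)
}

# Backward pass for categorical cross-entropy; y_onehot on the class order.
cnn_backward <- function(params, fwd, y_onehot) {
  cache <- fwd$cache
  grads <- list(conv = vector("list", length(params$conv)))
  do <- fwd$probs - y_onehot
  grads$fc2 <- list(W = outer(do, cache$h), b = do)
  dh <- drop(t(params$fc2$W) %*% do)
  if (!is.null(cache$dropout_mask)) dh <- dh * cache$dropout_mask
  dh <- dh * (cache$h_lin > 0)
  grads$fc1 <- list(W = outer(dh, cache$g), b = dh)
  dg <- drop(t(params$fc1$W) %*% dh)
  gd <- cache$gap_dim
  da <- array(rep(dg / (gd[1] * gd[2]), each = gd[1] * gd[2]), gd)
  for (i in rev(seq_along(params$conv))) {
    blk <- cache$blocks[[i]]
    dr <- cnn_maxpool2_backward(blk$idx, da, blk$in_dim[1], blk$in_dim[2])
    dz <- dr * (blk$pre_relu > 0)
    bw <- cnn_conv2d_backward(blk$input, params$conv[[i]]$W, dz, 3L)
    grads$conv[[i]] <- list(W = bw$dw, b = drop(bw$db))
    da <- bw$dx
  }
  grads
}

# Flatten/unflatten parameter lists for the Adam updater.
param_leaves <- function(p) {
  out <- list()
  for (i in seq_along(p$conv)) {
    out[[paste0("conv", i, ".W")]] <- p$conv[[i]]$W
    out[[paste0("conv", i, ".b")]] <- p$conv[[i]]$b
  }
  out[["fc1.W"]] <- p$fc1$W; out[["fc1.b"]] <- p$fc1$b
  out[["fc2.W"]] <- p$fc2$W; out[["fc2.b"]] <- p$fc2$b
  out
}

set_param_leaves <- function(p, leaves) {
  for (i in seq_along(p$conv)) {
    p$conv[[i]]$W <- leaves[[paste0("conv", i, ".W")]]
    p$conv[[i]]$b <- leaves[[paste0("conv", i, ".b")]]
  }
  p$fc1 <- list(W = leaves[["fc1.W"]], b = leaves[["fc1.b"]])
  p$fc2 <- list(W = leaves[["fc2.W"]], b = leaves[["fc2.b"]])
  p
}

adam_init <- function(params) {
  leaves <- param_leaves(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  pl <- param_leaves(params)
  gl <- param_leaves(grads)
  state$t <- state$t + 1L
  for (k in names(pl)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gl[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gl[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    pl[[k]] <- pl[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = set_param_leaves(params, pl), state = state)
}

# Sum two gradient trees (for minibatch accumulation).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  la <- param_leaves(a); lb <- param_leaves(b)
  set_param_leaves(a, Map(`+`, la, lb))
}

grad_scale <- function(g, s) {
  set_param_leaves(g, lapply(param_leaves(g), function(x) x * s))
}
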