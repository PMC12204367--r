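# Small 1-D convolutional network engine.
#
# Implements exactly the pieces the peak regressor and threshold classifier
# need: valid (unpadded) 1-D convolution, per-channel batch normalization,
# ReLU, width-2 max pooling, inverted dropout, dense layers, Adam, and
# weighted squared-error / binary-cross-entropy (with logits) losses.
# Activations are arrays of dim (batch, channels, length); convolution is
# evaluated as k shifted matrix products, which keeps everything inside
# BLAS calls.

nn_layer_conv <- function(in_ch, out_ch, kernel) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, kernel = kernel)
}
nn_layer_bn <- function(channels) list(type = "bn", channels = channels)
nn_layer_relu <- function() list(type = "relu")
nn_layer_pool <- function() list(type = "pool")
nn_layer_dropout <- function(p) list(type = "dropout", p = p)
nn_layer_flatten <- function() list(type = "flatten")
nn_layer_dense <- function(in_dim, out_dim) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim)
}

nn_init_layer <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- layer$in_ch * layer$kernel
    layer$W <- array(stats::rnorm(layer$out_ch * layer$in_ch * layer$kernel,
                                  sd = sqrt(2 / fan_in)),
                     dim = c(layer$out_ch, layer$in_ch, layer$kernel))
    layer$b <- numeric(layer$out_ch)
  } else if (layer$type == "bn") {
    layer$gamma <- rep(1, layer$channels)
    layer$beta <- numeric(layer$channels)
    layer$run_mean <- numeric(layer$channels)
    layer$run_var <- rep(1, layer$channels)
  } else if (layer$type == "dense") {
    layer$W <- matrix(stats::rnorm(layer$in_dim * layer$out_dim,
                                   sd = sqrt(2 / layer$in_dim)),
                      layer$in_dim, layer$out_dim)
    layer$b <- numeric(layer$out_dim)
  }
  layer
}

# Build a sequential conv net: conv blocks (conv, bn, relu, pool, dropout)
# followed by flatten and two dense layers (hidden ReLU, linear output).
nn_build_cnn <- function(input_len, channels, kernels, dropout = 0.25,
                         fc_units = 64, out_units = 1) {
  stopifnot(length(channels) == length(kernels))
  layers <- list()
  len <- input_len
  in_ch <- 1L
  for (i in seq_along(channels)) {
    layers <- c(layers, list(nn_layer_conv(in_ch, channels[i], kernels[i])))
    len <- len - kernels[i] + 1L
    layers <- c(layers, list(nn_layer_bn(channels[i]), nn_layer_relu(),
                             nn_layer_pool()))
    len <- len %/% 2L
    if (dropout > 0) layers <- c(layers, list(nn_layer_dropout(dropout)))
    in_ch <- channels[i]
  }
  if (len < 1L) stop("input too short for this architecture")
  layers <- c(layers, list(
    nn_layer_flatten(),
    nn_layer_dense(in_ch * len, fc_units),
    nn_layer_relu(),
    nn_layer_dense(fc_units, out_units)))
  structure(list(layers = lapply(layers, nn_init_layer),
                 input_len = input_len, out_units = out_units),
            class = "abr_nn")
}

conv_fwd <- function(x, W, b) {
  d <- dim(x); B <- d[1]; Cin <- d[2]; L <- d[3]
  Cout <- dim(W)[1]; k <- dim(W)[3]
  Lout <- L - k + 1L
  xp <- aperm(x, c(1, 3, 2))                       # (B, L, Cin)
  outp <- matrix(b, B * Lout, Cout, byrow = TRUE)
  for (j in seq_len(k)) {
    m <- matrix(xp[, j:(j + Lout - 1L), , drop = FALSE], B * Lout, Cin)
    Wj <- matrix(W[, , j], Cout, Cin)
    outp <- outp + m %*% t(Wj)
  }
  list(out = aperm(array(outp, c(B, Lout, Cout)), c(1, 3, 2)), xp = xp)
}

conv_bwd <- function(dout, xp, W) {
  Cout <- dim(W)[1]; Cin <- dim(W)[2]; k <- dim(W)[3]
  B <- dim(dout)[1]; Lout <- dim(dout)[3]
  doutp <- matrix(aperm(dout, c(1, 3, 2)), B * Lout, Cout)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  for (j in seq_len(k)) {
    m <- matrix(xp[, j:(j + Lout - 1L), , drop = FALSE], B * Lout, Cin)
    dW[, , j] <- crossprod(doutp, m)               # (Cout, Cin)
    dm <- doutp %*% matrix(W[, , j], Cout, Cin)    # (B*Lout, Cin)
    dxp[, j:(j + Lout - 1L), ] <- dxp[, j:(j + Lout - 1L), , drop = FALSE] +
      array(dm, c(B, Lout, Cin))
  }
  list(dx = aperm(dxp, c(1, 3, 2)), dW = dW, db = colSums(doutp))
}

bn_fwd <- function(x, layer, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  xm <- matrix(aperm(x, c(1, 3, 2)), B * L, C)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    layer$run_mean <- (1 - momentum) * layer$run_mean + momentum * mu
    layer$run_var <- (1 - momentum) * layer$run_var + momentum * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  ivar <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, ivar, "*")
  ym <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  out <- aperm(array(ym, c(B, L, C)), c(1, 3, 2))
  list(out = out, layer = layer, cache = list(xhat = xhat, ivar = ivar,
                                              dims = c(B, C, L)))
}

bn_bwd <- function(dout, layer, cache) {
  B <- cache$dims[1]; C <- cache$dims[2]; L <- cache$dims[3]
  dym <- matrix(aperm(dout, c(1, 3, 2)), B * L, C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  scale <- layer$gamma * cache$ivar
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * xhat)
  dxm <- sweep(dym - matrix(m1, B * L, C, byrow = TRUE) -
                 xhat * matrix(m2, B * L, C, byrow = TRUE), 2, scale, "*")
  dx <- aperm(array(dxm, c(B, L, C)), c(1, 3, 2))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(x) {
  d <- dim(x); L2 <- d[3] %/% 2L
  a <- x[, , seq(1L, 2L * L2, by = 2L), drop = FALSE]
  b <- x[, , seq(2L, 2L * L2, by = 2L), drop = FALSE]
  mask <- a >= b                                   # tie -> left sample
  list(out = pmax(a, b), mask = mask, in_len = d[3])
}

pool_bwd <- function(dout, mask, in_len) {
  d <- dim(dout); L2 <- d[3]
  dx <- array(0, c(d[1], d[2], in_len))
  dx[, , seq(1L, 2L * L2, by = 2L)] <- dout * mask
  dx[, , seq(2L, 2L * L2, by = 2L)] <- dout * !mask
  dx
}

nn_forward <- function(model, X, training = FALSE) {
  B <- nrow(X)
  a <- array(X, c(B, 1L, ncol(X)))
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$type == "conv") {
      f <- conv_fwd(a, ly$W, ly$b)
      caches[[i]] <- list(xp = f$xp)
      a <- f$out
    } else if (ly$type == "bn") {
      f <- bn_fwd(a, ly, training)
      model$layers[[i]] <- f$layer
      caches[[i]] <- f$cache
      a <- f$out
    } else if (ly$type == "relu") {
      caches[[i]] <- list(mask = a > 0)
      a <- a * caches[[i]]$mask
    } else if (ly$type == "pool") {
      f <- pool_fwd(a)
      caches[[i]] <- list(mask = f$mask, in_len = f$in_len)
      a <- f$out
    } else if (ly$type == "dropout") {
      if (training && ly$p > 0) {
        keep <- array(stats::runif(length(a)) >= ly$p, dim(a))
        caches[[i]] <- list(keep = keep, p = ly$p)
        a <- a * keep / (1 - ly$p)
      } else {
        caches[[i]] <- list(keep = NULL)
      }
    } else if (ly$type == "flatten") {
      caches[[i]] <- list(dims = dim(a))
      a <- matrix(a, dim(a)[1], prod(dim(a)[-1]))
    } else if (ly$type == "dense") {
      caches[[i]] <- list(x = a)
      a <- sweep(a %*% ly$W, 2, ly$b, "+")
    }
  }
  list(out = a, caches = caches, model = model)
}

nn_backward <- function(model, caches, dout) {
  grads <- vector("list", length(model$layers))
  da <- dout
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "conv") {
      g <- conv_bwd(da, ca$xp, ly$W)
      grads[[i]] <- list(W = g$dW, b = g$db)
      da <- g$dx
    } else if (ly$type == "bn") {
      g <- bn_bwd(da, ly, ca)
      grads[[i]] <- list(gamma = g$dgamma, beta = g$dbeta)
      da <- g$dx
    } else if (ly$type == "relu") {
      da <- da * ca$mask
    } else if (ly$type == "pool") {
      da <- pool_bwd(da, ca$mask, ca$in_len)
    } else if (ly$type == "dropout") {
      if (!is.null(ca$keep)) da <- da * ca$keep / (1 - ca$p)
    } else if (ly$type == "flatten") {
      da <- array(da, ca$dims)
    } else if (ly$type == "dense") {
      grads[[i]] <- list(W = crossprod(ca$x, da), b = colSums(da))
      da <- da %*% t(ly$W)
    }
  }
  grads
}

# Weighted losses; both return the scalar loss and d(loss)/d(raw output).
loss_mse <- function(pred, y, w) {
  w <- w / sum(w)
  r <- pred - y
  list(loss = sum(w * r^2), grad = matrix(2 * w * r, ncol = 1))
}

loss_bce_logits <- function(z, y, w) {
  w <- w / sum(w)
  p <- stats::plogis(z)
  eps <- 1e-12
  list(loss = -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))),
       grad = matrix(w * (p - y), ncol = 1))
}

nn_param_names <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"), dense = c("W", "b"), bn = c("gamma", "beta"),
         character(0))
}

nn_adam_init <- function(model) {
  lapply(model$layers, function(ly) {
    nm <- nn_param_names(ly)
    st <- list()
    for (p in nm) st[[p]] <- list(m = ly[[p]] * 0, v = ly[[p]] * 0)
    st
  })
}

nn_adam_step <- function(model, grads, state, t, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(model$layers)) {
    nm <- nn_param_names(model$layers[[i]])
    for (p in nm) {
      g <- grads[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(model = model, state = state)
}

nn_loss_on <- function(model, X, y, w, loss_fn, batch = 512L) {
  n <- nrow(X)
  tot <- 0; wtot <- sum(w)
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    out <- nn_forward(model, X[s:e, , drop = FALSE], training = FALSE)$out
    wb <- w[s:e]
    tot <- tot + loss_fn(out, y[s:e], wb)$loss * sum(wb)
  }
  tot / wtot
}

# Train with minibatch Adam and patience-based early stopping on the
# validation loss; weights from the best validation epoch are restored.
nn_fit <- function(model, X, y, Xval, yval, loss = c("mse", "bce"),
                   weights = NULL, val_weights = NULL, max_epochs = 80L,
                   patience = 25L, lr = 1e-3, batch_size = 64L,
                   lr_decay = 0.5, lr_decay_every = 30L, seed = 1L,
                   verbose = FALSE) {
  loss <- match.arg(loss)
  loss_fn <- if (loss == "mse") loss_mse else loss_bce_logits
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(val_weights)) val_weights <- rep(1, nrow(Xval))
  set.seed(seed)
  state <- nn_adam_init(model)
  t <- 0L
  best <- list(loss = Inf, epoch = 0L, layers = model$layers)
  since_improve <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (epoch in seq_len(max_epochs)) {
    # step decay sharpens late convergence of the localization nets
    lr_epoch <- lr * lr_decay^((epoch - 1L) %/% lr_decay_every)
    idx <- sample.int(n)
    ep_loss <- 0; ep_w <- 0
    for (s in seq(1L, n, by = batch_size)) {
      b <- idx[s:min(s + batch_size - 1L, n)]
      fw <- nn_forward(model, X[b, , drop = FALSE], training = TRUE)
      model <- fw$model                       # updated BN running stats
      lo <- loss_fn(fw$out, y[b], weights[b])
      if (!is.finite(lo$loss)) {
        stop("non-finite training loss at epoch ", epoch)
      }
      grads <- nn_backward(model, fw$caches, lo$grad)
      t <- t + 1L
      up <- nn_adam_step(model, grads, state, t, lr_epoch)
      model <- up$model; state <- up$state
      ep_loss <- ep_loss + lo$loss * sum(weights[b])
      ep_w <- ep_w + sum(weights[b])
    }
    vloss <- nn_loss_on(model, Xval, yval, val_weights, loss_fn)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / ep_w,
                                   val_loss = vloss))
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      ep_loss / ep_w, vloss))
    }
    if (vloss < best$loss) {
      best <- list(loss = vloss, epoch = epoch, layers = model$layers)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= patience) break
    }
  }
  model$layers <- best$layers
  model$best_epoch <- best$epoch
  model$stopped_epoch <- nrow(hist)
  model$history <- hist
  model
}

nn_predict <- function(model, X, batch = 1024L) {
  n <- nrow(X)
  out <- numeric(0)
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    out <- c(out,
             as.numeric(nn_forward(model, X[s:e, , drop = FALSE],
                                   training = FALSE)$out))
  }
  out
}

# Flatten / restore all trainable parameters (used by the gradient checks).
nn_get_params <- function(model) {
  unlist(lapply(model$layers, function(ly) {
    unlist(lapply(nn_param_names(ly), function(p) as.numeric(ly[[p]])))
  }))
}

nn_set_params <- function(model, theta) {
  pos <- 1L
  for (i in seq_along(model$layers)) {
    for (p in nn_param_names(model$layers[[i]])) {
      cur <- model$layers[[i]][[p]]
      k <- length(cur)
      model$layers[[i]][[p]] <- array(theta[pos:(pos + k - 1L)],
                                      dim = if (is.null(dim(cur))) k
                                            else dim(cur))
      if (is.null(dim(cur))) {
        model$layers[[i]][[p]] <- as.numeric(model$layers[[i]][[p]])
      }
      pos <- pos + k
    }
  }
  model
}

nn_flatten_grads <- function(model, grads) {
  out <- numeric(0)
  for (i in seq_along(model$layers)) {
    nm <- nn_param_names(model$layers[[i]])
    mapnm <- c(W = "W", b = "b", gamma = "gamma", beta = "beta")
    for (p in nm) out <- c(out, as.numeric(grads[[i]][[mapnm[[p]]]]))
  }
  out
}
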