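# Internal numerical engine for the temporal convolutional network.
#
# Layout: a batch of B windows of T time steps x C channels is processed as a
# (B*T) x C matrix whose rows are grouped by window with time contiguous.
# Dilated 1D convolution with kernel size k is then k shifted matrix products:
# for tap j with time offset o_j, Y += X[rows shifted by o_j] %*% W_j, with
# zero padding outside the window (implemented via an appended all-zero row).
# Batch normalization is per output channel over all rows of the batch.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

batch_to_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

# per-tap source-row indices for offset o within each length-T window;
# out-of-window positions point at the appended zero row (B*T + 1)
shift_index <- function(B, T, o) {
  t_new <- rep(seq_len(T), times = B) + o
  r <- seq_len(B * T) + o
  r[t_new < 1 | t_new > T] <- B * T + 1
  r
}

conv_offsets <- function(kernel, dilation) {
  # centered taps, e.g. kernel 3 -> offsets -d, 0, +d
  (seq_len(kernel) - (kernel + 1) / 2) * dilation
}

conv_forward <- function(Mpad, W, idx) {
  Y <- Mpad[idx[[1]], , drop = FALSE] %*% W[[1]]
  for (j in seq_along(W)[-1]) {
    Y <- Y + Mpad[idx[[j]], , drop = FALSE] %*% W[[j]]
  }
  Y
}

bn_forward_train <- function(Y, gamma, beta) {
  n <- nrow(Y)
  mu <- colMeans(Y)
  Yc <- Y - rep(mu, each = n)
  v <- colMeans(Yc^2)
  inv_sd <- 1 / sqrt(v + BN_EPS)
  xhat <- Yc * rep(inv_sd, each = n)
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = out, xhat = xhat, inv_sd = inv_sd, mu = mu, v = v)
}

bn_forward_eval <- function(Y, gamma, beta, run_mean, run_var) {
  n <- nrow(Y)
  inv_sd <- 1 / sqrt(run_var + BN_EPS)
  (Y - rep(run_mean, each = n)) * rep(gamma * inv_sd, each = n) + rep(beta, each = n)
}

bn_backward <- function(dout, cache, gamma) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(gamma, each = n)
  # standard batchnorm gradient
  dY <- (dxhat - rep(colMeans(dxhat), each = n) -
    xhat * rep(colMeans(dxhat * xhat), each = n)) * rep(cache$inv_sd, each = n)
  list(dY = dY, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

init_tcn_params <- function(config, n_channels, n_classes) {
  k <- config$kernel
  dil <- config$dilations
  f <- config$filters
  params <- list()
  c_in <- n_channels
  for (i in seq_along(dil)) {
    for (j in seq_len(k)) {
      params[[sprintf("blk%d_W%d", i, j)]] <-
        matrix(stats::rnorm(c_in * f, sd = sqrt(2 / (k * c_in))), c_in, f)
    }
    params[[sprintf("blk%d_gamma", i)]] <- rep(1, f)
    params[[sprintf("blk%d_beta", i)]] <- rep(0, f)
    c_in <- f
  }
  head_in <- f
  if (config$dense_units > 0) {
    params$hid_W <- matrix(
      stats::rnorm(head_in * config$dense_units, sd = sqrt(2 / head_in)),
      head_in, config$dense_units
    )
    params$hid_b <- rep(0, config$dense_units)
    head_in <- config$dense_units
  }
  params$out_W <- matrix(stats::rnorm(head_in * n_classes, sd = sqrt(2 / head_in)),
    head_in, n_classes
  )
  params$out_b <- rep(0, n_classes)
  params
}

init_bn_state <- function(config) {
  list(
    run_mean = lapply(seq_len(config$n_blocks), function(i) rep(0, config$filters)),
    run_var = lapply(seq_len(config$n_blocks), function(i) rep(1, config$filters))
  )
}

# forward pass in inference mode -> class probabilities (B x n_classes)
tcn_forward_eval <- function(model, x) {
  d <- dim(x)
  B <- d[1]; T <- d[2]
  cfg <- model$config
  M <- batch_to_matrix(x)
  for (i in seq_len(cfg$n_blocks)) {
    idx <- lapply(conv_offsets(cfg$kernel, cfg$dilations[i]), function(o) shift_index(B, T, o))
    Mpad <- rbind(M, 0)
    W <- lapply(seq_len(cfg$kernel), function(j) model$params[[sprintf("blk%d_W%d", i, j)]])
    Y <- conv_forward(Mpad, W, idx)
    Y <- bn_forward_eval(
      Y, model$params[[sprintf("blk%d_gamma", i)]],
      model$params[[sprintf("blk%d_beta", i)]],
      model$bn$run_mean[[i]], model$bn$run_var[[i]]
    )
    M <- pmax(Y, 0)
  }
  P <- rowsum(M, group = rep(seq_len(B), each = T)) / T
  if (cfg$dense_units > 0) {
    P <- pmax(P %*% model$params$hid_W + rep(model$params$hid_b, each = B), 0)
  }
  Z <- P %*% model$params$out_W + rep(model$params$out_b, each = B)
  softmax_rows(Z)
}

# one training step on a minibatch: forward (training mode), backward,
# returns gradients, loss, accuracy and updated batchnorm running stats
tcn_train_step <- function(model, x, y_idx) {
  d <- dim(x)
  B <- d[1]; T <- d[2]
  cfg <- model$config
  nb <- cfg$n_blocks
  drop_p <- cfg$dropout
  M <- batch_to_matrix(x)
  cache <- vector("list", nb)
  for (i in seq_len(nb)) {
    idx <- lapply(conv_offsets(cfg$kernel, cfg$dilations[i]), function(o) shift_index(B, T, o))
    Mpad <- rbind(M, 0)
    W <- lapply(seq_len(cfg$kernel), function(j) model$params[[sprintf("blk%d_W%d", i, j)]])
    Y <- conv_forward(Mpad, W, idx)
    bn <- bn_forward_train(
      Y, model$params[[sprintf("blk%d_gamma", i)]],
      model$params[[sprintf("blk%d_beta", i)]]
    )
    relu_mask <- bn$out > 0
    A <- bn$out * relu_mask
    if (drop_p > 0) {
      keep <- matrix(stats::runif(length(A)) >= drop_p, nrow(A), ncol(A))
      A <- A * keep / (1 - drop_p)
    } else {
      keep <- NULL
    }
    model$bn$run_mean[[i]] <- BN_MOMENTUM * model$bn$run_mean[[i]] + (1 - BN_MOMENTUM) * bn$mu
    model$bn$run_var[[i]] <- BN_MOMENTUM * model$bn$run_var[[i]] + (1 - BN_MOMENTUM) * bn$v
    cache[[i]] <- list(Mpad = Mpad, idx = idx, bn = bn, relu_mask = relu_mask, keep = keep)
    M <- A
  }
  group <- rep(seq_len(B), each = T)
  P <- rowsum(M, group = group) / T
  hid <- NULL
  H <- P
  if (cfg$dense_units > 0) {
    Zh <- P %*% model$params$hid_W + rep(model$params$hid_b, each = B)
    hid <- list(P = P, mask = Zh > 0)
    H <- Zh * hid$mask
  }
  Z <- H %*% model$params$out_W + rep(model$params$out_b, each = B)
  prob <- softmax_rows(Z)
  loss <- -mean(log(pmax(prob[cbind(seq_len(B), y_idx)], 1e-12)))
  acc <- mean(max.col(prob) == y_idx)

  grads <- list()
  dZ <- prob
  dZ[cbind(seq_len(B), y_idx)] <- dZ[cbind(seq_len(B), y_idx)] - 1
  dZ <- dZ / B
  grads$out_W <- crossprod(H, dZ)
  grads$out_b <- colSums(dZ)
  dH <- dZ %*% t(model$params$out_W)
  if (cfg$dense_units > 0) {
    dZh <- dH * hid$mask
    grads$hid_W <- crossprod(hid$P, dZh)
    grads$hid_b <- colSums(dZh)
    dP <- dZh %*% t(model$params$hid_W)
  } else {
    dP <- dH
  }
  dM <- dP[group, , drop = FALSE] / T
  for (i in rev(seq_len(nb))) {
    cc <- cache[[i]]
    if (!is.null(cc$keep)) dM <- dM * cc$keep / (1 - drop_p)
    dM <- dM * cc$relu_mask
    bnb <- bn_backward(dM, cc$bn, model$params[[sprintf("blk%d_gamma", i)]])
    grads[[sprintf("blk%d_gamma", i)]] <- bnb$dgamma
    grads[[sprintf("blk%d_beta", i)]] <- bnb$dbeta
    dY <- bnb$dY
    n_rows <- nrow(dY)
    dX <- matrix(0, n_rows, nrow(model$params[[sprintf("blk%d_W%d", i, 1)]]))
    for (j in seq_len(cfg$kernel)) {
      Wj <- model$params[[sprintf("blk%d_W%d", i, j)]]
      src <- cc$idx[[j]]
      ok <- src <= n_rows
      grads[[sprintf("blk%d_W%d", i, j)]] <-
        crossprod(cc$Mpad[src[ok], , drop = FALSE], dY[ok, , drop = FALSE])
      contrib <- dY[ok, , drop = FALSE] %*% t(Wj)
      rows <- src[ok]
      dX[rows, ] <- dX[rows, ] + contrib
    }
    dM <- dX
  }
  list(grads = grads, loss = loss, accuracy = acc, bn = model$bn)
}

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0
  )
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
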