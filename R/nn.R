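# Minimal 1-D convolutional network engine (forward/backward/Adam) built on
# base-R matrix algebra. Convolutions run as im2col gathers followed by BLAS
# matrix products; gradients scatter back through the same index map. The
# engine exists because the model spectrum studied here (direct, Gaussian,
# classification, ordinal heads over a shared residual backbone) needs full
# control over losses, heads and last-layer curvature.

#' Backbone configuration for the 1-D residual network
#'
#' A stem convolution followed by `n_blocks` residual blocks (two
#' convolutions each, batch-normalized, with a projection shortcut whenever
#' shape changes), global average pooling, and a small fully-connected head.
#' The product of `stem_stride` and `downsample` must divide `in_len`.
#'
#' @param in_leads,in_len input shape (leads x samples)
#' @param stem_channels,stem_kernel,stem_stride stem convolution
#' @param channels channel width per residual block
#' @param kernel convolution kernel length (samples)
#' @param downsample per-block temporal subsampling factor
#' @param head_hidden width of the hidden head layer
#' @param dropout dropout rate on the pooled feature vector
#' @return object of class `backbone_config`
#' @export
backbone_config <- function(in_leads = 8, in_len = 4096,
                            stem_channels = 32, stem_kernel = 17,
                            stem_stride = 2,
                            channels = c(64, 128, 196, 256),
                            kernel = 17,
                            downsample = c(4, 4, 4, 4),
                            head_hidden = 32, dropout = 0) {
  stopifnot(length(channels) == length(downsample))
  total_ds <- stem_stride * prod(downsample)
  if (in_len %% total_ds != 0) {
    stop("product of downsample factors must divide the input length",
         call. = FALSE)
  }
  structure(
    list(in_leads = in_leads, in_len = in_len,
         stem_channels = stem_channels, stem_kernel = stem_kernel,
         stem_stride = stem_stride, channels = channels, kernel = kernel,
         downsample = downsample, head_hidden = head_hidden,
         dropout = dropout),
    class = "backbone_config"
  )
}

#' Desk-scale ("tiny") backbone profile
#'
#' Two narrow residual blocks over 512-sample, 128 Hz inputs; trains in tens
#' of seconds on one CPU core while retaining the architecture of the full
#' model.
#' @param in_len input length in samples
#' @param dropout dropout rate on the pooled features
#' @export
backbone_tiny <- function(in_len = 512, dropout = 0) {
  backbone_config(in_leads = 8, in_len = in_len,
                  stem_channels = 12, stem_kernel = 9, stem_stride = 2,
                  channels = c(16, 24), kernel = 9, downsample = c(4, 4),
                  head_hidden = 16, dropout = dropout)
}

#' Training configuration
#'
#' @param epochs number of passes over the training set (default 30); the
#'   returned model is the checkpoint with the lowest validation loss
#' @param batch_size minibatch size
#' @param lr initial Adam learning rate
#' @param lr_factor,lr_patience reduce-on-plateau schedule: multiply the rate
#'   by `lr_factor` after `lr_patience` epochs without validation improvement
#' @param seed seed for initialization and batch shuffling
#' @export
train_config <- function(epochs = 30, batch_size = 32, lr = 1e-3,
                         lr_factor = 0.5, lr_patience = 4, seed = 1) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_factor = lr_factor, lr_patience = lr_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---------------------------------------------------------------------------
# layer constructors

conv_geom <- function(c_in, k, stride, pad, l_in) {
  l_pad <- l_in + 2L * pad
  l_out <- (l_pad - k) %/% stride + 1L
  # gather index into the padded (c_in x l_pad) plane; channel fastest,
  # then kernel offset, then output position
  l_idx <- rep(seq_len(l_out), each = c_in * k)
  k_idx <- rep(rep(seq_len(k), each = c_in), times = l_out)
  c_idx <- rep(seq_len(c_in), times = k * l_out)
  col <- (l_idx - 1L) * stride + k_idx
  idx <- c_idx + (col - 1L) * c_in
  list(idx = idx, l_out = l_out, l_pad = l_pad)
}

new_conv <- function(c_in, c_out, k, stride, pad, l_in) {
  g <- conv_geom(c_in, k, stride, pad, l_in)
  list(type = "conv", c_in = c_in, c_out = c_out, k = k, stride = stride,
       pad = pad, l_in = l_in, l_out = g$l_out, l_pad = g$l_pad, idx = g$idx,
       W = matrix(stats::rnorm(c_out * c_in * k, 0, sqrt(2 / (c_in * k))),
                  c_out, c_in * k),
       b = numeric(c_out))
}

new_bn <- function(c) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), momentum = 0.1, eps = 1e-5)
}

new_dense <- function(c_in, c_out, scale = sqrt(2 / c_in)) {
  list(type = "dense", c_in = c_in, c_out = c_out,
       W = matrix(stats::rnorm(c_out * c_in, 0, scale), c_out, c_in),
       b = numeric(c_out))
}

# ---------------------------------------------------------------------------
# primitive forward/backward

conv_fwd <- function(ly, x) {
  # x: (c_in, l_in, B)
  B <- dim(x)[3]
  if (ly$pad > 0) {
    xp <- array(0, c(ly$c_in, ly$l_pad, B))
    xp[, ly$pad + seq_len(ly$l_in), ] <- x
  } else xp <- x
  dim(xp) <- c(ly$c_in * ly$l_pad, B)
  Xc <- xp[ly$idx, , drop = FALSE]
  dim(Xc) <- c(ly$c_in * ly$k, ly$l_out * B)
  Y <- ly$W %*% Xc + ly$b
  dim(Y) <- c(ly$c_out, ly$l_out, B)
  list(out = Y, cache = Xc)
}

conv_bwd <- function(ly, cache, dY) {
  B <- dim(dY)[3]
  dim(dY) <- c(ly$c_out, ly$l_out * B)
  dW <- dY %*% t(cache)
  db <- rowSums(dY)
  dXc <- crossprod(ly$W, dY)
  dim(dXc) <- c(ly$c_in * ly$k * ly$l_out, B)
  rs <- rowsum(dXc, ly$idx)
  dxp <- matrix(0, ly$c_in * ly$l_pad, B)
  dxp[as.integer(rownames(rs)), ] <- rs
  dim(dxp) <- c(ly$c_in, ly$l_pad, B)
  dx <- if (ly$pad > 0) dxp[, ly$pad + seq_len(ly$l_in), , drop = FALSE] else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

bn_fwd <- function(ly, x, train) {
  dims <- dim(x); B <- dims[3]
  dim(x) <- c(dims[1], dims[2] * B)
  if (train) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc^2)
    inv_sd <- 1 / sqrt(v + ly$eps)
    xh <- xc * inv_sd
    ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
    ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * v
  } else {
    inv_sd <- 1 / sqrt(ly$run_var + ly$eps)
    xh <- (x - ly$run_mean) * inv_sd
  }
  y <- ly$gamma * xh + ly$beta
  dim(y) <- dims
  list(out = y, cache = list(xh = xh, inv_sd = inv_sd, dims = dims),
       layer = ly)
}

bn_bwd <- function(ly, cache, dY) {
  dims <- cache$dims
  dim(dY) <- c(dims[1], dims[2] * dims[3])
  xh <- cache$xh
  N <- ncol(dY)
  dgamma <- rowSums(dY * xh)
  dbeta <- rowSums(dY)
  dxh <- dY * ly$gamma
  dx <- (cache$inv_sd / N) * (N * dxh - rowSums(dxh) - xh * rowSums(dxh * xh))
  dim(dx) <- dims
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

gap_fwd <- function(x) {
  dims <- dim(x)
  f <- matrix(0, dims[1], dims[3])
  for (b in seq_len(dims[3])) f[, b] <- rowMeans(x[, , b, drop = TRUE])
  list(out = f, L = dims[2])
}

gap_bwd <- function(df, C, L, B) {
  aperm(array(df / L, dim = c(C, B, L)), c(1, 3, 2))
}

# ---------------------------------------------------------------------------
# network assembly

head_outputs <- function(kind, k) {
  switch(kind, direct = 1L, gaussian = 2L,
         classification = as.integer(k), ordinal = as.integer(k) - 1L)
}

#' @keywords internal
nn_build <- function(backbone, head_kind, k = NULL, seed = 1) {
  with_local_seed(seed, {
    bc <- backbone
    layers <- list()
    l_cur <- bc$in_len; c_cur <- bc$in_leads
    layers$stem_conv <- new_conv(c_cur, bc$stem_channels, bc$stem_kernel,
                                 bc$stem_stride, bc$stem_kernel %/% 2L, l_cur)
    l_cur <- layers$stem_conv$l_out; c_cur <- bc$stem_channels
    layers$stem_bn <- new_bn(c_cur)
    blocks <- list()
    for (i in seq_along(bc$channels)) {
      ch <- bc$channels[i]; ds <- bc$downsample[i]
      blk <- list(
        conv1 = new_conv(c_cur, ch, bc$kernel, ds, bc$kernel %/% 2L, l_cur),
        bn1 = new_bn(ch)
      )
      l_new <- blk$conv1$l_out
      blk$conv2 <- new_conv(ch, ch, bc$kernel, 1L, bc$kernel %/% 2L, l_new)
      blk$bn2 <- new_bn(ch)
      if (ds != 1L || ch != c_cur) {
        blk$proj <- new_conv(c_cur, ch, 1L, ds, 0L, l_cur)
        blk$proj_bn <- new_bn(ch)
      }
      blocks[[i]] <- blk
      l_cur <- l_new; c_cur <- ch
    }
    n_out <- head_outputs(head_kind, k)
    head <- list(
      fc1 = new_dense(c_cur, bc$head_hidden),
      fc2 = new_dense(bc$head_hidden, n_out, scale = 0.05)
    )
    if (head_kind == "gaussian") head$fc2$b[2] <- 0.55 # softplus ~ 1 at start
    structure(
      list(backbone = bc, head_kind = head_kind, k = k,
           layers = layers, blocks = blocks, head = head,
           feat_channels = c_cur, feat_len = l_cur, seed = seed),
      class = "ecgnet"
    )
  })
}

# Forward pass. Returns head output z (n_out x B); when grad = TRUE also a
# cache for the backward pass. `train` toggles batch-norm statistics and
# dropout.
nn_forward <- function(net, x, train = FALSE, grad = FALSE,
                       dropout_mask = NULL) {
  cc <- list()
  st <- conv_fwd(net$layers$stem_conv, x)
  bn <- bn_fwd(net$layers$stem_bn, st$out, train)
  if (train) net$layers$stem_bn <- bn$layer
  a <- bn$out; mask_stem <- a > 0; a <- a * mask_stem
  if (grad) cc$stem <- list(conv = st$cache, bn = bn$cache, mask = mask_stem)

  block_caches <- vector("list", length(net$blocks))
  for (i in seq_along(net$blocks)) {
    blk <- net$blocks[[i]]
    c1 <- conv_fwd(blk$conv1, a)
    b1 <- bn_fwd(blk$bn1, c1$out, train)
    if (train) net$blocks[[i]]$bn1 <- b1$layer
    m1 <- b1$out > 0
    h <- b1$out * m1
    c2 <- conv_fwd(blk$conv2, h)
    b2 <- bn_fwd(blk$bn2, c2$out, train)
    if (train) net$blocks[[i]]$bn2 <- b2$layer
    if (!is.null(blk$proj)) {
      pj <- conv_fwd(blk$proj, a)
      pb <- bn_fwd(blk$proj_bn, pj$out, train)
      if (train) net$blocks[[i]]$proj_bn <- pb$layer
      shortcut <- pb$out
      proj_cache <- list(conv = pj$cache, bn = pb$cache)
    } else {
      shortcut <- a
      proj_cache <- NULL
    }
    s <- b2$out + shortcut
    m2 <- s > 0
    a_new <- s * m2
    if (grad) {
      block_caches[[i]] <- list(conv1 = c1$cache, bn1 = b1$cache, mask1 = m1,
                                conv2 = c2$cache, bn2 = b2$cache,
                                proj = proj_cache, mask2 = m2)
    }
    a <- a_new
  }

  g <- gap_fwd(a)
  f <- g$out
  if (train && net$backbone$dropout > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::runif(length(f)) > net$backbone$dropout,
                             nrow(f)) / (1 - net$backbone$dropout)
    }
    f <- f * dropout_mask
  }
  h1 <- net$head$fc1$W %*% f + net$head$fc1$b
  mh <- h1 > 0
  h1r <- h1 * mh
  z <- net$head$fc2$W %*% h1r + net$head$fc2$b

  if (grad) {
    cc$blocks <- block_caches
    cc$gap_L <- g$L
    cc$feat <- f
    cc$dropout_mask <- dropout_mask
    cc$h1r <- h1r
    cc$mask_head <- mh
    cc$B <- dim(x)[3]
  }
  list(z = z, cache = cc, net = net, hidden = h1r)
}

# Backward pass from dz (n_out x B); returns gradients in the same structure
# as the parameters.
nn_backward <- function(net, cache, dz) {
  gr <- list(head = list(), blocks = vector("list", length(net$blocks)),
             layers = list())
  gr$head$fc2 <- list(W = dz %*% t(cache$h1r), b = rowSums(dz))
  dh1 <- crossprod(net$head$fc2$W, dz) * cache$mask_head
  gr$head$fc1 <- list(W = dh1 %*% t(cache$feat), b = rowSums(dh1))
  df <- crossprod(net$head$fc1$W, dh1)
  if (!is.null(cache$dropout_mask)) df <- df * cache$dropout_mask
  da <- gap_bwd(df, net$feat_channels, cache$gap_L, cache$B)

  for (i in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[i]]
    bc <- cache$blocks[[i]]
    ds <- da * bc$mask2
    # main path
    b2 <- bn_bwd(blk$bn2, bc$bn2, ds)
    c2 <- conv_bwd(blk$conv2, bc$conv2, b2$dx)
    dh <- c2$dx * bc$mask1
    b1 <- bn_bwd(blk$bn1, bc$bn1, dh)
    c1 <- conv_bwd(blk$conv1, bc$conv1, b1$dx)
    gb <- list(conv1 = c1$grads, bn1 = b1$grads,
               conv2 = c2$grads, bn2 = b2$grads)
    if (!is.null(blk$proj)) {
      pb <- bn_bwd(blk$proj_bn, bc$proj$bn, ds)
      pj <- conv_bwd(blk$proj, bc$proj$conv, pb$dx)
      gb$proj <- pj$grads
      gb$proj_bn <- pb$grads
      da <- c1$dx + pj$dx
    } else {
      da <- c1$dx + ds
    }
    gr$blocks[[i]] <- gb
  }

  ds <- da * cache$stem$mask
  bn <- bn_bwd(net$layers$stem_bn, cache$stem$bn, ds)
  cv <- conv_bwd(net$layers$stem_conv, cache$stem$conv, bn$dx)
  gr$layers$stem_bn <- bn$grads
  gr$layers$stem_conv <- cv$grads
  gr
}

# ---------------------------------------------------------------------------
# parameter bookkeeping: walk layers and apply an updater to (param, grad)

param_names <- function(layer) {
  switch(layer$type, conv = c("W", "b"), dense = c("W", "b"),
         bn = c("gamma", "beta"))
}

nn_apply_update <- function(net, grads, fun) {
  upd_layer <- function(layer, g, path) {
    for (p in param_names(layer)) {
      layer[[p]] <- fun(layer[[p]], g[[p]], paste(path, p, sep = "."))
    }
    layer
  }
  net$layers$stem_conv <- upd_layer(net$layers$stem_conv,
                                    grads$layers$stem_conv, "stem_conv")
  net$layers$stem_bn <- upd_layer(net$layers$stem_bn,
                                  grads$layers$stem_bn, "stem_bn")
  for (i in seq_along(net$blocks)) {
    for (nm in c("conv1", "bn1", "conv2", "bn2", "proj", "proj_bn")) {
      if (!is.null(net$blocks[[i]][[nm]])) {
        net$blocks[[i]][[nm]] <- upd_layer(net$blocks[[i]][[nm]],
                                           grads$blocks[[i]][[nm]],
                                           sprintf("b%d.%s", i, nm))
      }
    }
  }
  net$head$fc1 <- upd_layer(net$head$fc1, grads$head$fc1, "fc1")
  net$head$fc2 <- upd_layer(net$head$fc2, grads$head$fc2, "fc2")
  net
}

adam_new <- function() new.env(parent = emptyenv())

adam_update <- function(state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- (state$t %||% 0) + 1
  t <- state$t
  function(param, grad, key) {
    m <- state[[paste0(key, ".m")]] %||% (grad * 0)
    v <- state[[paste0(key, ".v")]] %||% (grad * 0)
    m <- beta1 * m + (1 - beta1) * grad
    v <- beta2 * v + (1 - beta2) * grad^2
    state[[paste0(key, ".m")]] <- m
    state[[paste0(key, ".v")]] <- v
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    param - lr * mh / (sqrt(vh) + eps)
  }
}

# ---------------------------------------------------------------------------
# training loop

target_matrix <- function(head_kind, y, k) {
  switch(head_kind,
    direct = , gaussian = y,
    classification = y, # integer classes
    ordinal = {
      Y <- vapply(y, function(cl) as.numeric(seq_len(k - 1) < cl),
                  numeric(k - 1)) # (k-1) x n cumulative encodings
      if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1)
      Y
    }
  )
}

batch_loss <- function(head_kind, z, yb) {
  switch(head_kind,
    direct = loss_grad_mse(z, yb),
    gaussian = loss_grad_gaussian(z, yb),
    classification = loss_grad_ce(z, yb),
    ordinal = loss_grad_ordinal(z, yb)
  )
}

slice_targets <- function(head_kind, Y, idx) {
  if (head_kind == "ordinal") Y[, idx, drop = FALSE] else Y[idx]
}

nn_eval_loss <- function(net, x, Y, head_kind, batch_size = 256) {
  n <- dim(x)[3]
  tot <- 0
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    z <- nn_forward(net, x[, , idx, drop = FALSE], train = FALSE)$z
    lb <- batch_loss(head_kind, z, slice_targets(head_kind, Y, idx))
    tot <- tot + lb$loss * length(idx)
  }
  tot / n
}

#' @keywords internal
nn_fit <- function(net, x_train, y_train, x_val, y_val, cfg) {
  head_kind <- net$head_kind
  Ytr <- target_matrix(head_kind, y_train, net$k)
  Yva <- target_matrix(head_kind, y_val, net$k)
  n <- dim(x_train)[3]
  state <- adam_new()
  lr <- cfg$lr
  best_val <- Inf; best_net <- net; since_best <- 0
  history <- numeric(cfg$epochs)
  with_local_seed(child_seed(cfg$seed, 7919), {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (s in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[s:min(s + cfg$batch_size - 1, n)]
        if (length(idx) < 2) next # batch norm needs >= 2 examples
        xb <- x_train[, , idx, drop = FALSE]
        fw <- nn_forward(net, xb, train = TRUE, grad = TRUE)
        net <- fw$net # updated running stats
        lb <- batch_loss(head_kind, fw$z, slice_targets(head_kind, Ytr, idx))
        gr <- nn_backward(net, fw$cache, lb$dz)
        net <- nn_apply_update(net, gr, adam_update(state, lr))
      }
      vl <- nn_eval_loss(net, x_val, Yva, head_kind)
      history[ep] <- vl
      if (vl < best_val) {
        best_val <- vl; best_net <- net; since_best <- 0
      } else {
        since_best <- since_best + 1
        if (since_best >= cfg$lr_patience) {
          lr <- lr * cfg$lr_factor
          since_best <- 0
        }
      }
    }
  })
  best_net$history <- list(val_loss = history, best_val = best_val,
                           best_epoch = which.min(history))
  best_net
}

# Batched eval-mode head outputs (n_out x n)
nn_predict_raw <- function(net, x, batch_size = 256) {
  n <- dim(x)[3]
  out <- NULL
  feats <- NULL
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    fw <- nn_forward(net, x[, , idx, drop = FALSE], train = FALSE)
    out <- cbind(out, fw$z)
    feats <- cbind(feats, fw$hidden)
  }
  list(z = out, hidden = feats)
}
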