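# Classical baselines over vectorized traces: PCA feature reduction feeding
# linear / gradient-boosting / random-forest regressors, and batch-wise
# trained linear and 3-layer MLP models on the raw flattened input.

flatten_traces <- function(x) {
  n <- dim(x)[3]
  out <- matrix(0, n, dim(x)[1] * dim(x)[2])
  for (i in seq_len(n)) out[i, ] <- as.numeric(x[, , i])
  out
}

# randomized range-finder SVD: top-k right singular vectors of a centered
# n x d matrix without forming the full decomposition
randomized_pca <- function(X, k, seed, oversample = 16) {
  l <- min(ncol(X), k + oversample)
  with_local_seed(seed, {
    Om <- matrix(stats::rnorm(ncol(X) * l), ncol(X), l)
    Q <- qr.Q(qr(X %*% Om))
    B <- crossprod(Q, X) # l x d
    sv <- svd(B, nu = 0, nv = min(k, nrow(B)))
    sv$v[, seq_len(min(k, ncol(sv$v))), drop = FALSE]
  })
}

#' PCA-reduced classical regression baselines
#'
#' Vectorizes the preprocessed traces, fits PCA (randomized SVD) on the
#' training set only, reduces to `n_components` dimensions, and fits linear
#' regression, gradient boosting and a random forest on the reduced
#' features. The fitted feature map is applied unchanged to the test set.
#'
#' @param data a [prepare_model_data()] result
#' @param n_components reduced feature dimension (default 256)
#' @param test_partition which partition to report on
#' @param seed seed for PCA sketching and the tree ensembles
#' @param gbm_rounds,rf_trees budgets for the tree baselines; boosting uses
#'   validation-based early stopping, mirroring the best-epoch selection of
#'   the deep models
#' @return list with `report` (data.frame model/mse/mae) and `predictions`
#'   (named list of test-set prediction vectors)
#' @export
fit_pca_baselines <- function(data, n_components = 256,
                              test_partition = "random_test", seed = 1,
                              gbm_rounds = 150, rf_trees = 200) {
  Xtr <- flatten_traces(data$train$x)
  Xva <- flatten_traces(data$val$x)
  Xte <- flatten_traces(data[[test_partition]]$x)
  ytr <- data$train$y
  yva <- data$val$y
  yte <- data[[test_partition]]$y
  k <- min(n_components, nrow(Xtr) - 1L, ncol(Xtr))

  mu <- colMeans(Xtr)
  Xtr <- sweep(Xtr, 2, mu)
  Xva <- sweep(Xva, 2, mu)
  Xte <- sweep(Xte, 2, mu)
  V <- randomized_pca(Xtr, k, seed)
  Ztr <- Xtr %*% V
  Zva <- Xva %*% V
  Zte <- Xte %*% V

  preds <- list()
  fit <- stats::lm.fit(cbind(1, Ztr), ytr)
  preds$linear <- as.numeric(cbind(1, Zte) %*% fit$coefficients)

  # boosting-round selection on the validation partition (same protocol as
  # the deep models' best-validation-epoch checkpointing)
  val_mse <- function(nr) {
    b <- xgboost::xgboost(x = Ztr, y = ytr, nrounds = nr, max_depth = 3,
                          learning_rate = 0.1, verbosity = 0, nthread = 1)
    mean((stats::predict(b, Zva) - yva)^2)
  }
  grid <- unique(pmin(gbm_rounds, c(10, 25, 50, 100, gbm_rounds)))
  best_nr <- grid[which.min(vapply(grid, val_mse, numeric(1)))]
  bst <- xgboost::xgboost(x = Ztr, y = ytr, nrounds = best_nr,
                          max_depth = 3, learning_rate = 0.1,
                          verbosity = 0, nthread = 1)
  preds$gradient_boosting <- as.numeric(stats::predict(bst, Zte))

  colnames(Ztr) <- colnames(Zte) <- paste0("pc", seq_len(ncol(Ztr)))
  rf <- ranger::ranger(y = ytr, x = as.data.frame(Ztr), num.trees = rf_trees,
                       seed = child_seed(seed, 2), num.threads = 1)
  preds$random_forest <- as.numeric(stats::predict(
    rf, data = as.data.frame(Zte))$predictions)

  report <- do.call(rbind, lapply(names(preds), function(nm) {
    data.frame(model = nm,
               mse = mean((preds[[nm]] - yte)^2),
               mae = mean(abs(preds[[nm]] - yte)),
               stringsAsFactors = FALSE)
  }))
  list(report = report, predictions = preds, n_components = k)
}

# --- small dense network trained batch-wise (shared protocol with the deep
# models: Adam, minibatches, best-validation checkpoint) ---------------------

dense_forward <- function(layers, X, grad = FALSE) {
  a <- t(X) # features x batch
  caches <- list()
  for (i in seq_along(layers)) {
    z <- layers[[i]]$W %*% a + layers[[i]]$b
    if (i < length(layers)) {
      mask <- z > 0
      if (grad) caches[[i]] <- list(a = a, mask = mask)
      a <- z * mask
    } else {
      if (grad) caches[[i]] <- list(a = a)
      a <- z
    }
  }
  list(out = a, caches = caches)
}

dense_backward <- function(layers, caches, dz) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    grads[[i]] <- list(W = dz %*% t(caches[[i]]$a), b = rowSums(dz))
    if (i > 1) {
      dz <- crossprod(layers[[i]]$W, dz) * caches[[i - 1]]$mask
    }
  }
  grads
}

dense_fit <- function(Xtr, ytr, Xval, yval, hidden, cfg) {
  sizes <- c(ncol(Xtr), hidden, 1L)
  with_local_seed(cfg$seed, {
    layers <- lapply(seq_len(length(sizes) - 1L), function(i) {
      new_dense(sizes[i], sizes[i + 1],
                scale = if (i == length(sizes) - 1L) 0.05
                        else sqrt(2 / sizes[i]))
    })
    state <- adam_new()
    n <- nrow(Xtr); lr <- cfg$lr
    best <- Inf; best_layers <- layers; since <- 0
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (s in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[s:min(s + cfg$batch_size - 1, n)]
        fw <- dense_forward(layers, Xtr[idx, , drop = FALSE], grad = TRUE)
        r <- fw$out[1, ] - ytr[idx]
        dz <- matrix(2 * r / length(idx), 1)
        gr <- dense_backward(layers, fw$caches, dz)
        upd <- adam_update(state, lr)
        for (i in seq_along(layers)) {
          layers[[i]]$W <- upd(layers[[i]]$W, gr[[i]]$W, sprintf("l%d.W", i))
          layers[[i]]$b <- upd(layers[[i]]$b, gr[[i]]$b, sprintf("l%d.b", i))
        }
      }
      vl <- mean((dense_forward(layers, Xval)$out[1, ] - yval)^2)
      if (vl < best) { best <- vl; best_layers <- layers; since <- 0 }
      else {
        since <- since + 1
        if (since >= cfg$lr_patience) { lr <- lr * cfg$lr_factor; since <- 0 }
      }
    }
    best_layers
  })
}

#' Batch-wise linear and 3-layer MLP baselines on raw traces
#'
#' Trains, with the same minibatch protocol as the deep models (Adam,
#' z-scored targets, best-validation checkpoint), a linear model and a
#' 3-layer multilayer perceptron on the flattened raw ECG input.
#'
#' @param data a [prepare_model_data()] result
#' @param cfg a [train_config()]
#' @param mlp_hidden hidden widths of the two internal MLP layers
#' @param test_partition partition to report on
#' @return list with `report` (data.frame model/mse/mae) and `predictions`
#' @export
fit_batchwise_baselines <- function(data, cfg = train_config(),
                                    mlp_hidden = c(64, 16),
                                    test_partition = "random_test") {
  Xtr <- flatten_traces(data$train$x)
  Xva <- flatten_traces(data$val$x)
  Xte <- flatten_traces(data[[test_partition]]$x)
  ytr <- apply_normalizer(data$train$y, data$norm)
  yva <- apply_normalizer(data$val$y, data$norm)
  yte <- data[[test_partition]]$y

  preds <- list()
  lin <- dense_fit(Xtr, ytr, Xva, yva, hidden = integer(0), cfg)
  preds$batch_linear <- invert_normalizer(
    as.numeric(dense_forward(lin, Xte)$out), data$norm)

  mcfg <- cfg; mcfg$seed <- child_seed(cfg$seed, 3)
  mlp <- dense_fit(Xtr, ytr, Xva, yva, hidden = mlp_hidden, mcfg)
  preds$mlp3 <- invert_normalizer(
    as.numeric(dense_forward(mlp, Xte)$out), data$norm)

  report <- do.call(rbind, lapply(names(preds), function(nm) {
    data.frame(model = nm,
               mse = mean((preds[[nm]] - yte)^2),
               mae = mean(abs(preds[[nm]] - yte)),
               stringsAsFactors = FALSE)
  }))
  list(report = report, predictions = preds)
}
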