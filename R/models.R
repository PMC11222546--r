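#' Assemble model-ready train/val/test arrays from a preprocessed cohort
#'
#' Runs the dataset-construction chain: ECG/lab linking within the +/-60 min
#' window with median target assignment, patient-level random/temporal
#' splitting at the cutoff date (with post-cutoff ECG removal), first-ECG
#' selection in evaluation partitions, and target z-scoring fitted on the
#' training targets only.
#'
#' @param cohort a preprocessed [ecg_cohort()]
#' @param window_minutes linking half-window
#' @param cutoff_date temporal split cutoff
#' @param val_fraction_of_dev fraction of development patients held out for
#'   validation
#' @param seed split seed
#' @return object of class `linked_dataset`: per-partition arrays
#'   `x` (leads x samples x n) and target vectors `y` (raw scale), the
#'   normalizer, linked tables, splits and per-partition `n_valid`
#' @export
prepare_model_data <- function(cohort, window_minutes = 60,
                               cutoff_date = "2017-01-01",
                               val_fraction_of_dev = 0.10, seed = 1) {
  linked <- link_ecg_lab(cohort$ecgs, cohort$labs, window_minutes)
  splits <- split_patients(cohort$patients, cohort$ecgs, cutoff_date,
                           val_fraction_of_dev = val_fraction_of_dev,
                           seed = seed)
  parts <- select_eval_ecgs(linked, cohort$ecgs, splits)
  norm <- fit_normalizer(parts$train$target)

  take <- function(df) {
    rows <- cohort$ecgs$trace_row[match(df$ecg_id, cohort$ecgs$ecg_id)]
    list(
      x = cohort$traces[, , rows, drop = FALSE],
      y = df$target,
      ecg_id = df$ecg_id,
      patient_id = df$patient_id,
      n_valid = if (!is.null(cohort$ecgs$n_valid))
        cohort$ecgs$n_valid[rows] else rep(dim(cohort$traces)[2], length(rows))
    )
  }
  structure(
    list(train = take(parts$train), val = take(parts$val),
         random_test = take(parts$random_test),
         temporal_test = take(parts$temporal_test),
         norm = norm, splits = splits, linked = linked,
         analyte = cohort$config$analyte),
    class = "linked_dataset"
  )
}

#' @export
print.linked_dataset <- function(x, ...) {
  cat(sprintf("<linked_dataset> train %d / val %d / random_test %d / temporal_test %d ECGs\n",
              length(x$train$y), length(x$val$y),
              length(x$random_test$y), length(x$temporal_test$y)))
  invisible(x)
}

new_model_state <- function(net, head_kind, norm, cfg, scheme = NULL) {
  structure(
    list(net = net, head_kind = head_kind, norm = norm, cfg = cfg,
         scheme = scheme, history = net$history),
    class = "ecgnet_model"
  )
}

check_nonempty <- function(data) {
  if (length(data$train$y) == 0) stop("empty training set", call. = FALSE)
}

#' Train the direct regression model
#'
#' ResNet backbone plus a scalar head, trained with MSE on z-scored targets;
#' the returned state is the epoch checkpoint with the lowest validation
#' loss.
#'
#' @param data a [prepare_model_data()] result
#' @param backbone a [backbone_config()]
#' @param cfg a [train_config()]
#' @return an `ecgnet_model`
#' @export
train_direct <- function(data, backbone = backbone_tiny(), cfg = train_config()) {
  check_nonempty(data)
  ytr <- apply_normalizer(data$train$y, data$norm)
  yva <- apply_normalizer(data$val$y, data$norm)
  net <- nn_build(backbone, "direct", seed = cfg$seed)
  net <- nn_fit(net, data$train$x, ytr, data$val$x, yva, cfg)
  new_model_state(net, "direct", data$norm, cfg)
}

#' Train the heteroscedastic Gaussian model
#'
#' Adds a variance output to the regression head and minimizes the Gaussian
#' negative log-likelihood; the predicted variance is the aleatoric
#' uncertainty estimate. Raw variance outputs map through
#' `softplus(x) + 1e-6` to stay positive.
#'
#' @inheritParams train_direct
#' @return an `ecgnet_model`
#' @export
train_gaussian <- function(data, backbone = backbone_tiny(), cfg = train_config()) {
  check_nonempty(data)
  ytr <- apply_normalizer(data$train$y, data$norm)
  yva <- apply_normalizer(data$val$y, data$norm)
  net <- nn_build(backbone, "gaussian", seed = cfg$seed)
  net <- nn_fit(net, data$train$x, ytr, data$val$x, yva, cfg)
  new_model_state(net, "gaussian", data$norm, cfg)
}

#' Train a k-class classifier on discretized targets
#'
#' Targets are assigned to the intervals of `scheme` (on the raw
#' concentration scale) and the model is trained with cross-entropy.
#'
#' @inheritParams train_direct
#' @param scheme an [build_scheme()] interval scheme
#' @return an `ecgnet_model`
#' @export
train_classifier <- function(data, scheme, backbone = backbone_tiny(),
                             cfg = train_config()) {
  check_nonempty(data)
  ytr <- assign_class(data$train$y, scheme)
  yva <- assign_class(data$val$y, scheme)
  net <- nn_build(backbone, "classification", k = scheme$k, seed = cfg$seed)
  net <- nn_fit(net, data$train$x, ytr, data$val$x, yva, cfg)
  new_model_state(net, "classification", data$norm, cfg, scheme)
}

#' Train a rank-consistent ordinal regression model
#'
#' `k - 1` sigmoid threshold outputs trained with binary cross-entropy
#' against cumulative encodings; decoding counts thresholds exceeding 0.5.
#'
#' @inheritParams train_classifier
#' @return an `ecgnet_model`
#' @export
train_ordinal <- function(data, scheme, backbone = backbone_tiny(),
                          cfg = train_config()) {
  check_nonempty(data)
  ytr <- assign_class(data$train$y, scheme)
  yva <- assign_class(data$val$y, scheme)
  net <- nn_build(backbone, "ordinal", k = scheme$k, seed = cfg$seed)
  net <- nn_fit(net, data$train$x, ytr, data$val$x, yva, cfg)
  new_model_state(net, "ordinal", data$norm, cfg, scheme)
}

#' Predict with a trained model
#'
#' Output depends on the head: direct regression returns de-normalized
#' concentrations; the Gaussian head returns a data.frame with `mean` and
#' `sd` on the concentration scale; classification returns class
#' probabilities, the argmax class and its representative concentration;
#' ordinal returns threshold probabilities, the decoded class and its
#' representative concentration.
#'
#' @param object an `ecgnet_model`
#' @param x trace array `leads x samples x n`
#' @param ... unused
#' @export
predict.ecgnet_model <- function(object, x, ...) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  raw <- nn_predict_raw(object$net, x)
  z <- raw$z
  switch(object$head_kind,
    direct = invert_normalizer(as.numeric(z[1, ]), object$norm),
    gaussian = {
      s2 <- softplus(z[2, ]) + VAR_FLOOR
      data.frame(mean = invert_normalizer(as.numeric(z[1, ]), object$norm),
                 sd = sqrt(s2) * object$norm$sd)
    },
    classification = {
      zs <- sweep(z, 2, apply(z, 2, max))
      p <- exp(zs); p <- sweep(p, 2, colSums(p), "/")
      cls <- apply(p, 2, which.max)
      list(probs = t(p), class = cls,
           value = class_to_value(cls, object$scheme))
    },
    ordinal = {
      p <- sigmoid(z)
      cls <- ordinal_decode(p)
      list(threshold_probs = t(p), class = cls,
           value = class_to_value(cls, object$scheme))
    }
  )
}

#' Extract last-layer features of the mean head
#'
#' The post-ReLU hidden activations feeding the final linear layer, used by
#' the last-layer Laplace approximation.
#'
#' @param model an `ecgnet_model`
#' @param x trace array
#' @return `hidden x n` feature matrix
#' @export
model_features <- function(model, x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1)
  nn_predict_raw(model$net, x)$hidden
}

#' Save / load a trained model
#'
#' Single-file RDS archive of parameters, normalization, scheme and training
#' provenance; loading reproduces predictions bitwise.
#'
#' @param model an `ecgnet_model`
#' @param path file path
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
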