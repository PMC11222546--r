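#' Regression metrics report
#'
#' MSE, MAE, Pearson R and Spearman rho (midrank ties). With degenerate
#' (constant) predictions or targets the correlations are undefined and
#' reported as NA with a warning.
#'
#' @param preds predicted concentrations
#' @param targets observed concentrations
#' @return list of class `metrics_report`: mse, mae, pearson_r,
#'   spearman_rho, n
#' @export
regression_metrics <- function(preds, targets) {
  stopifnot(length(preds) == length(targets))
  err <- preds - targets
  r <- rho <- NA_real_
  if (stats::sd(preds) == 0 || stats::sd(targets) == 0) {
    warning("constant predictions or targets: correlations undefined",
            call. = FALSE)
  } else {
    r <- stats::cor(preds, targets)
    rho <- stats::cor(preds, targets, method = "spearman")
  }
  structure(list(mse = mean(err^2), mae = mean(abs(err)),
                 pearson_r = r, spearman_rho = rho,
                 n = length(targets)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n=%d  MSE=%.4g  MAE=%.4g  R=%.3f  rho=%.3f\n",
              x$n, x$mse, x$mae, x$pearson_r, x$spearman_rho))
  invisible(x)
}

#' Metrics stratified by age decade and sex
#'
#' Reports, per stratum, the MAE of normalized targets (so values are
#' comparable across analytes) and the stratum's target standard deviation
#' — target variability rising with age explains most of the age trend in
#' the error.
#'
#' @param preds,targets concentrations
#' @param ages,sexes per-example covariates
#' @param age_bins left-closed bin edges (last bin open-ended)
#' @param norm a `norm_params` used to normalize; fitted on `targets` if NULL
#' @return data.frame: age_bin, sex, n, mae_normalized, target_sd
#' @export
stratified_metrics <- function(preds, targets, ages, sexes,
                               age_bins = c(18, 30, 40, 50, 60, 70, 80, Inf),
                               norm = NULL) {
  norm <- norm %||% fit_normalizer(targets)
  pn <- apply_normalizer(preds, norm)
  tn <- apply_normalizer(targets, norm)
  bin <- cut(ages, age_bins, right = FALSE, include.lowest = TRUE)
  out <- expand.grid(age_bin = levels(bin), sex = unique(sexes),
                     stringsAsFactors = FALSE)
  out$n <- 0L; out$mae_normalized <- NA_real_; out$target_sd <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- !is.na(bin) & bin == out$age_bin[i] & sexes == out$sex[i]
    out$n[i] <- sum(sel)
    if (out$n[i] > 0) {
      out$mae_normalized[i] <- mean(abs(pn[sel] - tn[sel]))
      out$target_sd[i] <- stats::sd(targets[sel])
    }
  }
  out
}

#' Area under the ROC curve (midrank Mann-Whitney estimator)
#'
#' @param scores higher score = more likely positive
#' @param labels logical (or 0/1) event indicators
#' @return AUROC in `[0, 1]`; NA if only one class is present
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores) # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  data.frame(fpr = c(0, fp / max(1, sum(!labels))),
             tpr = c(0, tp / max(1, sum(labels))))
}

#' Cumulative ROC family over discretized classes
#'
#' For each threshold `i = 1..k-1`, the event is `true class <= i`; the
#' score is the model's cumulative probability mass on classes `<= i`
#' (classification head) or one minus the i-th threshold probability
#' (ordinal head). The AUmROC is the arithmetic mean of the k-1 AUROCs.
#'
#' @param probs n x k class-probability matrix (classification) or
#'   n x (k-1) threshold-probability matrix (ordinal)
#' @param true_classes integer classes in 1..k
#' @param k number of classes
#' @param type "classification" or "ordinal"
#' @return object of class `roc_family`: per-threshold AUROCs and curves,
#'   and `aumroc`
#' @export
cumulative_roc <- function(probs, true_classes, k,
                           type = c("classification", "ordinal")) {
  type <- match.arg(type)
  probs <- as.matrix(probs)
  aurocs <- numeric(k - 1)
  curves <- vector("list", k - 1)
  for (i in seq_len(k - 1)) {
    score <- if (type == "classification") {
      rowSums(probs[, seq_len(i), drop = FALSE])
    } else {
      1 - probs[, i]
    }
    ev <- true_classes <= i
    aurocs[i] <- auroc(score, ev)
    curves[[i]] <- roc_points(score, ev)
  }
  structure(list(k = k, aurocs = aurocs,
                 aumroc = mean(aurocs, na.rm = TRUE), curves = curves),
            class = "roc_family")
}

#' Hypo/hyper binary AUROC pair
#'
#' Scores each abnormality direction against the clinical bounds of a
#' [build_binary_tasks()] pair; the average of the two AUROCs is the k = 2
#' point of the AUmROC-versus-k curve.
#'
#' @param hypo_scores,hyper_scores per-example scores, higher = more likely
#'   abnormal in that direction
#' @param targets observed concentrations
#' @param tasks a `binary_task_pair`
#' @return list: hypo_auroc, hyper_auroc, average
#' @export
binary_auroc_pair <- function(hypo_scores, hyper_scores, targets, tasks) {
  lab <- binary_labels(tasks, targets)
  h1 <- auroc(hypo_scores, lab$hypo)
  h2 <- auroc(hyper_scores, lab$hyper)
  list(hypo_auroc = h1, hyper_auroc = h2, average = mean(c(h1, h2)))
}
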