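#' Gaussian negative log-likelihood
#'
#' `sum_i [ 0.5 * log(2 * pi * var_i) + (y_i - mean_i)^2 / (2 * var_i) ]`,
#' the training criterion of the heteroscedastic Gaussian model.
#'
#' @param mean predicted means
#' @param variance predicted variances, strictly positive
#' @param targets observed values
#' @return scalar total NLL
#' @export
gaussian_nll <- function(mean, variance, targets) {
  stopifnot(length(mean) == length(targets), length(variance) == length(targets))
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    stop("variances must be strictly positive", call. = FALSE)
  }
  sum(0.5 * log(2 * pi * variance) + (targets - mean)^2 / (2 * variance))
}

#' Multiclass cross-entropy
#'
#' Mean over examples of `-log p[true class]`.
#'
#' @param probs n x k matrix of class probabilities (rows sum to 1)
#' @param classes integer class labels in 1..k
#' @export
cross_entropy <- function(probs, classes) {
  stopifnot(nrow(probs) == length(classes))
  p <- probs[cbind(seq_along(classes), classes)]
  mean(-log(pmax(p, 1e-12)))
}

#' Binary cross-entropy
#'
#' Mean over all entries of `-(t*log(p) + (1-t)*log(1-p))`.
#'
#' @param probs probabilities in (0,1)
#' @param targets binary targets of the same shape
#' @export
binary_cross_entropy <- function(probs, targets) {
  stopifnot(length(probs) == length(targets))
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  mean(-(targets * log(p) + (1 - targets) * log(1 - p)))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

VAR_FLOOR <- 1e-6

# --- internal training losses: value + gradient wrt head output rows -------

loss_grad_mse <- function(z, y) {
  r <- z[1, ] - y
  list(loss = mean(r^2), dz = matrix(2 * r / length(y), 1))
}

loss_grad_gaussian <- function(z, y) {
  mu <- z[1, ]; raw <- z[2, ]
  s2 <- softplus(raw) + VAR_FLOOR
  n <- length(y)
  nll <- 0.5 * log(2 * pi * s2) + (y - mu)^2 / (2 * s2)
  dmu <- (mu - y) / s2 / n
  ds2 <- (0.5 / s2 - (y - mu)^2 / (2 * s2^2)) / n
  draw <- ds2 * sigmoid(raw)
  list(loss = mean(nll), dz = rbind(dmu, draw))
}

loss_grad_ce <- function(z, classes) {
  # z: k x B logits
  zs <- sweep(z, 2, apply(z, 2, max))
  p <- exp(zs)
  p <- sweep(p, 2, colSums(p), "/")
  B <- ncol(z)
  idx <- cbind(classes, seq_len(B))
  loss <- mean(-log(pmax(p[idx], 1e-12)))
  dz <- p
  dz[idx] <- dz[idx] - 1
  list(loss = loss, dz = dz / B)
}

loss_grad_ordinal <- function(z, targets) {
  # z: (k-1) x B logits; targets: (k-1) x B cumulative encodings
  p <- sigmoid(z)
  B <- ncol(z)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loss <- sum(-(targets * log(pc) + (1 - targets) * log(1 - pc))) / B
  list(loss = loss, dz = (p - targets) / B)
}
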