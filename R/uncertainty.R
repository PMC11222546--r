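#' Train an ensemble of Gaussian models
#'
#' Members share data, backbone and training configuration and differ only
#' in seed (default 5 members). The ensemble underlies all three
#' uncertainty estimators: aleatoric Gaussian, epistemic ensemble and
#' epistemic last-layer Laplace.
#'
#' @param data a [prepare_model_data()] result
#' @param backbone a [backbone_config()]
#' @param cfg a [train_config()]; member seeds are derived from `base_seed`
#' @param n_members ensemble size
#' @param base_seed base seed the member seeds are derived from
#' @return object of class `ecgnet_ensemble`
#' @export
train_ensemble <- function(data, backbone = backbone_tiny(),
                           cfg = train_config(), n_members = 5,
                           base_seed = cfg$seed) {
  members <- vector("list", n_members)
  for (i in seq_len(n_members)) {
    mcfg <- cfg
    mcfg$seed <- child_seed(base_seed, i)
    members[[i]] <- train_gaussian(data, backbone, mcfg)
  }
  structure(list(members = members, base_seed = base_seed,
                 norm = data$norm),
            class = "ecgnet_ensemble")
}

ensemble_member_preds <- function(ensemble, x) {
  lapply(ensemble$members, function(m) predict(m, x))
}

#' Ensemble mean prediction
#'
#' @param ensemble an `ecgnet_ensemble`
#' @param x trace array
#' @return mean over members of the predicted means (concentration scale)
#' @export
ensemble_predict <- function(ensemble, x) {
  preds <- ensemble_member_preds(ensemble, x)
  rowMeans(vapply(preds, function(p) p$mean, numeric(dim(x)[3])))
}

#' Aleatoric Gaussian uncertainty
#'
#' Per example, the average over ensemble members of the predicted variance
#' `sigma^2(x)`, reported on the concentration scale (normalized variance
#' times the squared target-normalization sd).
#'
#' @inheritParams ensemble_predict
#' @return variance per example
#' @export
aleatoric_gaussian <- function(ensemble, x) {
  preds <- ensemble_member_preds(ensemble, x)
  rowMeans(vapply(preds, function(p) p$sd^2, numeric(dim(x)[3])))
}

#' Epistemic ensemble uncertainty
#'
#' Per example, the population variance across members of the predicted mean
#' (concentration scale). A single-member ensemble has zero epistemic
#' variance by construction.
#'
#' @inheritParams ensemble_predict
#' @return variance per example
#' @export
epistemic_ensemble <- function(ensemble, x) {
  mu <- vapply(ensemble_member_preds(ensemble, x),
               function(p) p$mean, numeric(dim(x)[3]))
  if (!is.matrix(mu)) mu <- matrix(mu, nrow = 1)
  rowMeans(mu^2) - rowMeans(mu)^2
}

#' Last-layer Laplace posterior for a linear-Gaussian layer
#'
#' Core conjugate computation: given features `phi` (p x n), targets `y`,
#' per-example observation variances and a scalar prior precision, the
#' posterior precision of the last-layer weights is the generalized
#' Gauss-Newton curvature plus the prior,
#' `Sigma^{-1} = sum_i phi_i phi_i' / s2_i + tau * I`.
#' With `prior_precision = "marglik"`, tau maximizes the exact log marginal
#' likelihood of the corresponding Bayesian linear regression over a log
#' grid.
#'
#' @param phi p x n feature matrix (include a constant row for the bias)
#' @param y length-n targets
#' @param noise_var scalar or length-n observation variances
#' @param prior_precision positive scalar, or "marglik"
#' @return object of class `laplace_posterior` with fields `cov`,
#'   `precision`, `prior_precision`
#' @export
laplace_last_layer <- function(phi, y, noise_var = 1,
                               prior_precision = "marglik") {
  if (!is.matrix(phi)) phi <- matrix(phi, nrow = 1)
  n <- ncol(phi); p <- nrow(phi)
  s2 <- rep(noise_var, length.out = n)
  if (any(s2 <= 0)) stop("noise variances must be positive", call. = FALSE)
  phiw <- sweep(phi, 2, s2, "/")
  H <- tcrossprod(phiw, phi) # sum phi phi' / s2
  b <- as.numeric(phiw %*% y)

  log_evidence <- function(tau) {
    A <- H + diag(tau, p)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    m <- backsolve(ch, forwardsolve(t(ch), b))
    -0.5 * n * log(2 * pi) - 0.5 * sum(log(s2)) +
      0.5 * p * log(tau) - sum(log(diag(ch))) -
      0.5 * (sum(y^2 / s2) - sum(b * m))
  }
  if (identical(prior_precision, "marglik")) {
    taus <- 10^seq(-3, 4, length.out = 29)
    ev <- vapply(taus, log_evidence, numeric(1))
    tau <- taus[which.max(ev)]
  } else {
    stopifnot_scalar_pos(prior_precision, "prior_precision")
    tau <- prior_precision
  }
  A <- H + diag(tau, p)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    A <- A + diag(1e-8 * max(diag(A)), p)
    ch <- chol(A) # raises if still singular
  }
  S <- chol2inv(ch)
  structure(list(cov = S, precision = A, prior_precision = tau),
            class = "laplace_posterior")
}

#' Fit the last-layer Laplace approximation to one ensemble member
#'
#' The trained member is treated as the MAP estimate; curvature is the
#' generalized Gauss-Newton Hessian of the training Gaussian NLL restricted
#' to the final linear layer of the mean head (features are the post-ReLU
#' hidden activations plus a bias constant; per-example noise variances are
#' the member's own predicted variances).
#'
#' @param member a Gaussian-head `ecgnet_model`
#' @param data a [prepare_model_data()] result (training partition is used)
#' @param prior_precision scalar, or "marglik" (default)
#' @return a `laplace_posterior`
#' @export
fit_laplace <- function(member, data, prior_precision = "marglik") {
  stopifnot(identical(member$head_kind, "gaussian"))
  phi <- rbind(model_features(member, data$train$x), 1)
  y <- apply_normalizer(data$train$y, member$norm)
  s2 <- (predict(member, data$train$x)$sd / member$norm$sd)^2
  laplace_last_layer(phi, y, s2, prior_precision)
}

#' Linearized Laplace predictive variance
#'
#' Per example, `phi(x)' Sigma phi(x)` for each member's posterior, averaged
#' over members and reported on the concentration scale.
#'
#' @param ensemble an `ecgnet_ensemble`
#' @param posteriors list of `laplace_posterior`, one per member
#' @param x trace array
#' @return variance per example
#' @export
epistemic_laplace <- function(ensemble, posteriors, x) {
  stopifnot(length(posteriors) == length(ensemble$members))
  n <- dim(x)[3]
  acc <- numeric(n)
  for (i in seq_along(ensemble$members)) {
    phi <- rbind(model_features(ensemble$members[[i]], x), 1)
    v <- colSums(phi * (posteriors[[i]]$cov %*% phi))
    acc <- acc + v * ensemble$members[[i]]$norm$sd^2
  }
  acc / length(ensemble$members)
}

#' All three uncertainty estimates for a test set
#'
#' @inheritParams epistemic_laplace
#' @return data.frame with mean_prediction, aleatoric_gaussian,
#'   epistemic_ensemble and (if posteriors given) epistemic_laplace columns
#'   (variances, concentration scale)
#' @export
uncertainty_estimates <- function(ensemble, x, posteriors = NULL) {
  out <- data.frame(
    mean_prediction = ensemble_predict(ensemble, x),
    aleatoric_gaussian = aleatoric_gaussian(ensemble, x),
    epistemic_ensemble = epistemic_ensemble(ensemble, x)
  )
  if (!is.null(posteriors)) {
    out$epistemic_laplace <- epistemic_laplace(ensemble, posteriors, x)
  }
  out
}
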