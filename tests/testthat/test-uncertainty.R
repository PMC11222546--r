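test_that("last-layer Laplace matches conjugate Bayesian linear regression", {
  set.seed(14)
  p <- 6; n <- 120; tau <- 2.5; s2 <- 1.0
  phi <- matrix(rnorm(p * n), p, n) # identity backbone: features = inputs
  w <- rnorm(p)
  y <- as.numeric(crossprod(phi, w)) + rnorm(n, 0, sqrt(s2))
  post <- laplace_last_layer(phi, y, noise_var = s2, prior_precision = tau)
  # closed-form oracle computed independently via solve()
  S_oracle <- solve(phi %*% t(phi) / s2 + tau * diag(p))
  expect_lt(max(abs(post$cov - S_oracle)) / max(abs(S_oracle)), 1e-6)
  # predictive variance at new inputs
  phi_new <- matrix(rnorm(p * 10), p, 10)
  v <- colSums(phi_new * (post$cov %*% phi_new))
  v_oracle <- diag(t(phi_new) %*% S_oracle %*% phi_new)
  expect_equal(v, v_oracle, tolerance = 1e-6)
})

test_that("the prior dominates in the large-precision limit", {
  set.seed(15)
  phi <- matrix(rnorm(4 * 50), 4, 50)
  y <- rnorm(50)
  post <- laplace_last_layer(phi, y, 1, prior_precision = 1e10)
  phi_new <- matrix(rnorm(4 * 5), 4, 5)
  v <- colSums(phi_new * (post$cov %*% phi_new))
  expect_true(all(v < 1e-8))
})

test_that("duplicating the training set halves the posterior covariance", {
  set.seed(16)
  phi <- matrix(rnorm(5 * 60), 5, 60)
  y <- rnorm(60)
  p1 <- laplace_last_layer(phi, y, 1, prior_precision = 1e-8)
  p2 <- laplace_last_layer(cbind(phi, phi), c(y, y), 1, prior_precision = 1e-8)
  expect_equal(p2$cov, p1$cov / 2, tolerance = 1e-6)
})

test_that("marginal-likelihood tuning recovers a sensible prior precision", {
  set.seed(17)
  p <- 4; n <- 400
  phi <- rbind(matrix(rnorm((p - 1) * n), p - 1, n), 1)
  w <- rnorm(p, 0, 1)
  y <- as.numeric(crossprod(phi, w)) + rnorm(n, 0, 0.5)
  post <- laplace_last_layer(phi, y, 0.25, prior_precision = "marglik")
  # weights drawn from unit-variance prior: tau should land near 1
  expect_gt(post$prior_precision, 0.05)
  expect_lt(post$prior_precision, 20)
})

test_that("ensemble uncertainties match brute-force member statistics", {
  d <- fixture_small_data()
  cfg <- train_config(epochs = 3, seed = 21)
  ens <- train_ensemble(d, backbone_tiny(), cfg, n_members = 3)
  x <- d$random_test$x
  member_means <- vapply(ens$members, function(m) predict(m, x)$mean,
                         numeric(dim(x)[3]))
  member_vars <- vapply(ens$members, function(m) predict(m, x)$sd^2,
                        numeric(dim(x)[3]))
  # arithmetic oracles: population variance / plain mean across members
  epi_oracle <- apply(member_means, 1, function(v) mean((v - mean(v))^2))
  ale_oracle <- rowMeans(member_vars)
  expect_equal(epistemic_ensemble(ens, x), epi_oracle, tolerance = 1e-10)
  expect_equal(aleatoric_gaussian(ens, x), ale_oracle, tolerance = 1e-10)
  expect_true(all(epistemic_ensemble(ens, x) >= 0))
  # ensemble mean prediction is the member average
  expect_equal(ensemble_predict(ens, x), rowMeans(member_means),
               tolerance = 1e-12)
})

test_that("a single-member ensemble has zero epistemic variance", {
  d <- fixture_small_data()
  ens1 <- train_ensemble(d, backbone_tiny(),
                         train_config(epochs = 2, seed = 23), n_members = 1)
  v <- epistemic_ensemble(ens1, d$random_test$x)
  expect_equal(v, rep(0, length(v)), tolerance = 1e-12)
})

test_that("estimates are invariant to test-batch ordering", {
  d <- fixture_small_data()
  cfg <- train_config(epochs = 2, seed = 25)
  ens <- train_ensemble(d, backbone_tiny(), cfg, n_members = 2)
  post <- lapply(ens$members, fit_laplace, data = d)
  x <- d$random_test$x
  set.seed(1)
  perm <- sample(dim(x)[3])
  u1 <- uncertainty_estimates(ens, x, post)
  u2 <- uncertainty_estimates(ens, x[, , perm, drop = FALSE], post)
  expect_equal(u2$aleatoric_gaussian, u1$aleatoric_gaussian[perm])
  expect_equal(u2$epistemic_ensemble, u1$epistemic_ensemble[perm])
  expect_equal(u2$epistemic_laplace, u1$epistemic_laplace[perm])
})
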