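test_that("Gaussian NLL matches its analytic values", {
  expect_equal(gaussian_nll(1, 1, 1), 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(gaussian_nll(0, 1, 1), 0.5 * log(2 * pi) + 0.5,
               tolerance = 1e-12)
  expect_error(gaussian_nll(0, 0, 1), "positive")
  expect_error(gaussian_nll(0, -1, 1), "positive")
})

test_that("losses match independent brute-force evaluations", {
  set.seed(11)
  n <- 100
  mu <- rnorm(n); s2 <- rexp(n) + 0.1; y <- rnorm(n)
  # density oracle: sum of -log Gaussian densities via dnorm
  oracle <- -sum(dnorm(y, mu, sqrt(s2), log = TRUE))
  expect_equal(gaussian_nll(mu, s2, y), oracle, tolerance = 1e-10)

  k <- 4
  logits <- matrix(rnorm(n * k), n, k)
  probs <- exp(logits) / rowSums(exp(logits))
  cls <- sample.int(k, n, replace = TRUE)
  ce_oracle <- mean(vapply(seq_len(n), function(i) -log(probs[i, cls[i]]),
                           numeric(1)))
  expect_equal(cross_entropy(probs, cls), ce_oracle, tolerance = 1e-10)

  p <- runif(n, 0.01, 0.99); t <- rbinom(n, 1, 0.5)
  bce_oracle <- mean(-(t * log(p) + (1 - t) * log(1 - p)))
  expect_equal(binary_cross_entropy(p, t), bce_oracle, tolerance = 1e-12)
})

test_that("training losses backpropagate exact gradients through the network", {
  bc <- backbone_config(in_leads = 2, in_len = 32, stem_channels = 3,
                        stem_kernel = 3, stem_stride = 2, channels = c(4, 5),
                        kernel = 3, downsample = c(2, 2), head_hidden = 5)
  set.seed(99)
  x <- array(rnorm(2 * 32 * 6), c(2, 32, 6))
  for (kind in c("direct", "gaussian", "classification", "ordinal")) {
    k <- if (kind %in% c("classification", "ordinal")) 4 else NULL
    net <- ecglyte:::nn_build(bc, kind, k = k, seed = 3)
    y <- switch(kind, direct = rnorm(6), gaussian = rnorm(6),
                sample.int(4, 6, replace = TRUE))
    Y <- ecglyte:::target_matrix(kind, y, k)
    lossfn <- function(n) {
      fw <- ecglyte:::nn_forward(n, x, train = TRUE, grad = TRUE)
      list(val = ecglyte:::batch_loss(kind, fw$z, Y), fw = fw)
    }
    r <- lossfn(net)
    gr <- ecglyte:::nn_backward(net, r$fw$cache, r$val$dz)
    # finite-difference oracle on representative parameters
    eps <- 1e-6
    probe <- list(
      list(get = function(n) n$blocks[[1]]$conv1$W[2, 4],
           set = function(n, v) { n$blocks[[1]]$conv1$W[2, 4] <- v; n },
           g = gr$blocks[[1]]$conv1$W[2, 4]),
      list(get = function(n) n$head$fc2$W[1, 2],
           set = function(n, v) { n$head$fc2$W[1, 2] <- v; n },
           g = gr$head$fc2$W[1, 2]),
      list(get = function(n) n$layers$stem_bn$gamma[2],
           set = function(n, v) { n$layers$stem_bn$gamma[2] <- v; n },
           g = gr$layers$stem_bn$gamma[2])
    )
    for (pb in probe) {
      v0 <- pb$get(net)
      fp <- lossfn(pb$set(net, v0 + eps))$val$loss
      fm <- lossfn(pb$set(net, v0 - eps))$val$loss
      fd <- (fp - fm) / (2 * eps)
      expect_equal(unname(pb$g), fd, tolerance = 1e-4)
    }
  }
})
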