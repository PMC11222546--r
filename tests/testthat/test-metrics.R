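test_that("regression metrics have the expected exact values", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(m$mse, m$mae), c(0, 0))
  expect_equal(c(m$pearson_r, m$spearman_rho), c(1, 1))
  y <- c(2, 5, 3, 9)
  expect_warning(mc <- regression_metrics(rep(4, 4), y), "undefined")
  expect_equal(mc$mse, mean((4 - y)^2))
  expect_true(is.na(mc$pearson_r))
})

test_that("metrics match brute-force formula evaluations", {
  p <- c(1, 2, 3, 4); y <- c(2, 2, 4, 3)
  m <- regression_metrics(p, y)
  expect_equal(m$mse, sum((p - y)^2) / 4, tolerance = 1e-12)
  expect_equal(m$mae, sum(abs(p - y)) / 4, tolerance = 1e-12)
  r_oracle <- sum((p - mean(p)) * (y - mean(y))) /
    sqrt(sum((p - mean(p))^2) * sum((y - mean(y))^2))
  expect_equal(m$pearson_r, r_oracle, tolerance = 1e-12)
  rho_oracle <- {
    rp <- rank(p); ry <- rank(y)
    sum((rp - mean(rp)) * (ry - mean(ry))) /
      sqrt(sum((rp - mean(rp))^2) * sum((ry - mean(ry))^2))
  }
  expect_equal(m$spearman_rho, rho_oracle, tolerance = 1e-12)
})

test_that("AUROC equals the brute-force pair-counting U statistic", {
  set.seed(3)
  s <- rnorm(80); l <- rbinom(80, 1, 0.4) == 1
  pairs <- 0; wins <- 0
  for (i in which(l)) for (j in which(!l)) {
    pairs <- pairs + 1
    wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(auroc(s, l), wins / pairs, tolerance = 1e-12)
  expect_equal(auroc(s, l), as.numeric(pROC::auc(pROC::roc(
    response = l, predictor = s, quiet = TRUE, direction = "<"))),
    tolerance = 1e-12)
  # label flip symmetry
  expect_equal(auroc(s, !l), 1 - auroc(s, l), tolerance = 1e-12)
  expect_true(is.na(auroc(s, rep(TRUE, 80))))
})

test_that("cumulative ROC behaves at the extremes and at chance", {
  k <- 4; n <- 2000
  set.seed(9)
  cls <- sample.int(k, n, replace = TRUE)
  # perfectly ordered scores: cumulative probabilities decreasing in class
  probs <- t(vapply(cls, function(cl) {
    p <- rep(0.001, k); p[cl] <- 1; p / sum(p)
  }, numeric(k)))
  roc <- cumulative_roc(probs, cls, k)
  expect_equal(roc$aurocs, rep(1, k - 1))
  expect_equal(roc$aumroc, 1)
  # random scores: each AUROC within 0.5 +/- 0.05
  rnd <- matrix(rexp(n * k), n)
  rnd <- rnd / rowSums(rnd)
  roc2 <- cumulative_roc(rnd, cls, k)
  expect_true(all(abs(roc2$aurocs - 0.5) < 0.05))
})

test_that("the k=2 case reduces to standard binary AUROC", {
  set.seed(5)
  y <- runif(300, 2.5, 6.5)
  score_hypo <- -y + rnorm(300, 0, 0.4)  # higher = more likely low
  score_hyper <- y + rnorm(300, 0, 0.4)
  tasks <- build_binary_tasks(analyte_profile("potassium"))
  pair <- binary_auroc_pair(score_hypo, score_hyper, y, tasks)
  lab <- binary_labels(tasks, y)
  expect_equal(pair$hypo_auroc, auroc(score_hypo, lab$hypo))
  expect_equal(pair$hyper_auroc, auroc(score_hyper, lab$hyper))
  expect_equal(pair$average, mean(c(pair$hypo_auroc, pair$hyper_auroc)))
  # ordinal threshold probabilities with k=2 give the same AUROC as the
  # mean of the cumulative family with one threshold
  p1 <- matrix(plogis(y - 4), ncol = 1)
  fam <- cumulative_roc(p1, ifelse(y > 4, 2L, 1L), 2, type = "ordinal")
  expect_equal(fam$aumroc, auroc(1 - p1[, 1], y <= 4))
})

test_that("sparsification is anchored, monotone under oracle ordering, flat under noise", {
  set.seed(12)
  err <- abs(rnorm(400))
  sp <- sparsification(err, err) # oracle: uncertainty = |error|
  expect_equal(sp$mae[1], mean(err))
  expect_true(all(diff(sp$mae) <= 1e-12))
  # independent uncertainty: curve flat within a resampling envelope
  devs <- replicate(200, {
    u <- runif(400)
    s <- sparsification(err, u)
    max(abs(s$mae - mean(err)))
  })
  sp2 <- sparsification(err, runif(400))
  expect_lte(max(abs(sp2$mae - mean(err))), quantile(devs, 0.999))
})

test_that("calibration coverage matches construction and limits", {
  set.seed(21)
  n <- 4000
  mu <- rnorm(n); s2 <- rexp(n) + 0.2
  y <- rnorm(n, mu, sqrt(s2))
  cal <- calibration_curve(mu, s2, y)
  # binomial error bound at each level
  for (i in seq_len(nrow(cal))) {
    se <- sqrt(cal$nominal[i] * (1 - cal$nominal[i]) / n)
    expect_lt(abs(cal$empirical[i] - cal$nominal[i]), 4 * se + 0.01)
  }
  expect_true(all(calibration_curve(mu, rep(1e-12, n), y)$empirical < 0.01))
  expect_true(all(calibration_curve(mu, rep(1e12, n), y)$empirical > 0.999))
})

test_that("uncertainty-error correlation handles proportional, independent and constant cases", {
  set.seed(7)
  se <- rexp(500)
  r <- uncertainty_error_correlation(list(aleatoric_gaussian = 2 * se), se)
  expect_equal(r$correlation[1], 1, tolerance = 1e-12)
  r2 <- uncertainty_error_correlation(
    list(aleatoric_gaussian = rexp(500), epistemic_ensemble = rexp(500)), se)
  expect_true(all(abs(r2$correlation) < 0.15))
  expect_equal(nrow(r2), 3) # two singles + one aleatoric+epistemic sum
  expect_warning(
    r3 <- uncertainty_error_correlation(list(aleatoric_gaussian = rep(1, 500)), se),
    "undefined")
  expect_true(is.na(r3$correlation[1]))
})

test_that("SNR noise injection realizes the requested power ratio", {
  set.seed(2)
  x <- array(rnorm(8 * 256 * 5), c(8, 256, 5))
  for (snr in c(10, 1)) {
    xn <- perturb_noise(x, snr, seed = 4)
    for (i in 1:5) {
      p_sig <- mean(x[, , i]^2)
      p_noise <- mean((xn[, , i] - x[, , i])^2)
      # power oracle: the realized ratio is exact by construction
      expect_lt(abs(p_sig / p_noise - snr) / snr, 1e-9)
    }
  }
  # snr -> infinity: perturbation -> 0
  x_inf <- perturb_noise(x, 1e12, seed = 4)
  expect_lt(max(abs(x_inf - x)), 1e-4)
  # padded tail stays zero
  xp <- x; xp[, 200:256, ] <- 0
  xn <- perturb_noise(xp, 1, seed = 5)
  expect_true(all(xn[, 200:256, ] == 0))
})

test_that("masking zeroes exactly the requested number of samples per lead", {
  set.seed(6)
  x <- array(rnorm(8 * 256 * 4) + 1, c(8, 256, 4)) # no pre-existing zeros
  expect_identical(perturb_mask(x, 0, seed = 1), x)
  x1 <- perturb_mask(x, 1, seed = 1)
  expect_true(all(x1 == 0))
  for (mode in c("contiguous", "scattered")) {
    xm <- perturb_mask(x, 0.25, seed = 3, mode = mode)
    for (i in 1:4) {
      zeros_per_lead <- rowSums(xm[, , i] == 0)
      expect_equal(zeros_per_lead, rep(round(0.25 * 256), 8))
    }
    if (mode == "contiguous") {
      z <- which(xm[1, , 1] == 0)
      expect_equal(z, seq(min(z), max(z)))
    }
  }
})
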