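# targets with exact population moments mean 4, sd 0.5
targets45 <- c(3.5, 4.5)

test_that("interval bounds follow the mu +/- 2 sigma / evenly-spaced rule", {
  s3 <- build_scheme(3, targets45)
  expect_equal(s3$bounds, c(3.0, 5.0))
  s5 <- build_scheme(5, targets45)
  expect_equal(s5$bounds, c(3.0, 3 + 2 / 3, 3 + 4 / 3, 5.0))
  s4 <- build_scheme(4, targets45)
  expect_length(s4$bounds, 3)
  expect_true(all(diff(s4$bounds) > 0))
  expect_error(build_scheme(2, targets45), "k >= 3")
  expect_error(build_scheme(3, rep(4, 10)), "sigma is zero")
})

test_that("interval width shrinks as 4*sigma/(k-2)", {
  for (k in 4:10) {
    s <- build_scheme(k, targets45)
    expect_equal(max(diff(s$bounds)), 4 * 0.5 / (k - 2))
  }
})

test_that("binary task bounds use the clinical hypo/hyper definitions", {
  pk <- build_binary_tasks(analyte_profile("potassium"))
  expect_equal(c(pk$hypo_bound, pk$hyper_bound), c(3.5, 5.5))
  ca <- build_binary_tasks(analyte_profile("calcium"))
  expect_equal(c(ca$hypo_bound, ca$hyper_bound), c(2.0, 2.75))
  # boundary value is not abnormal under the strict-inequality convention
  lab <- binary_labels(pk, c(3.5, 3.49, 5.5, 5.51))
  expect_equal(lab$hypo, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(lab$hyper, c(FALSE, FALSE, FALSE, TRUE))
  # creatinine falls back to mu +/- 2 sigma of the training targets
  cr <- build_binary_tasks(analyte_profile("creatinine"),
                           train_targets = c(80, 120))
  expect_equal(c(cr$hypo_bound, cr$hyper_bound), c(60, 140))
  expect_equal(cr$source, "mu_2sigma")
})

test_that("class assignment matches a linear-scan oracle", {
  s <- build_scheme(6, targets45)
  y <- runif(1000, 2, 6)
  got <- assign_class(y, s)
  oracle <- vapply(y, function(v) 1L + sum(s$bounds < v), integer(1))
  expect_identical(got, oracle)
  expect_equal(assign_class(2.0, s), 1L)
  expect_equal(assign_class(6.0, s), s$k)
  # boundary values take the lower class
  expect_equal(assign_class(s$bounds[2], s), 2L)
})

test_that("ordinal encode/decode are consistent for all classes and k", {
  for (k in 2:10) {
    for (cl in seq_len(k)) {
      enc <- ordinal_encode(cl, k)
      expect_length(enc, k - 1)
      # definition oracle: target_j = 1 iff class > j
      expect_equal(enc, as.numeric(cl > seq_len(k - 1)))
      expect_equal(ordinal_decode(enc), cl)
    }
  }
  expect_equal(ordinal_encode(1, 5), rep(0, 4))
  expect_equal(ordinal_encode(5, 5), rep(1, 4))
  expect_equal(ordinal_encode(3, 5), c(1, 1, 0, 0))
})

test_that("decoding counts exceeded thresholds and is rank-consistent", {
  expect_equal(ordinal_decode(rep(0, 4)), 1L)
  expect_equal(ordinal_decode(rep(1, 4)), 5L)
  probs <- c(0.9, 0.8, 0.3, 0.6)
  expect_equal(ordinal_decode(probs), 1L + sum(ifelse(probs > 0.5, 1, 0)))
  expect_equal(ordinal_decode(probs), 4L)
  # monotone: elementwise-increasing probabilities never decrease the class
  set.seed(31)
  for (i in 1:200) {
    p <- runif(5)
    q <- pmin(1, p + runif(5, 0, 0.5))
    expect_gte(ordinal_decode(q), ordinal_decode(p))
  }
})

test_that("class representatives are midpoints with documented edge handling", {
  y <- c(2.0, 3.5, 4.5, 7.0) # mean 4.25, range [2, 7]
  s <- build_scheme(3, y)
  expect_equal(class_to_value(2, s), mean(s$bounds))
  expect_equal(class_to_value(1, s), (2.0 + s$bounds[1]) / 2)
  expect_equal(class_to_value(3, s), (s$bounds[2] + 7.0) / 2)
  # interior representatives re-assign to their own class
  s6 <- build_scheme(6, targets45)
  for (cl in 2:5) {
    expect_equal(assign_class(class_to_value(cl, s6), s6), cl)
  }
})
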