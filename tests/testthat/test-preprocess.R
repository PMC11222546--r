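mk_record <- function(x, fs) {
  if (!is.matrix(x)) x <- matrix(x, 1, dimnames = list("I", NULL))
  ecg_record(x, fs = fs)
}

test_that("short traces are zero-padded at the end to the target length", {
  x <- matrix(rnorm(8 * 4000), 8,
              dimnames = list(c("I", "II", paste0("V", 1:6)), NULL))
  rec <- ecg_record(x, fs = 400)
  out <- preprocess_trace(rec, target_fs = 400, target_len = 4096)
  expect_equal(ncol(out$trace), 4096)
  expect_true(all(out$trace[, 4001:4096] == 0))
  expect_equal(attr(out, "n_valid"), 4000)
})

test_that("traces longer than the target length are rejected", {
  x <- matrix(rnorm(8 * 5000), 8,
              dimnames = list(c("I", "II", paste0("V", 1:6)), NULL))
  expect_error(preprocess_trace(ecg_record(x, fs = 400),
                                target_fs = 400, target_len = 4096),
               "too long")
})

test_that("the high-pass removes constant offsets", {
  x <- matrix(5, 8, 512, dimnames = list(c("I", "II", paste0("V", 1:6)), NULL))
  out <- preprocess_trace(ecg_record(x, fs = 128), target_fs = 128,
                          target_len = 512)
  expect_lt(max(abs(rowMeans(out$trace))), 1e-3 * 5)
})

test_that("the notch suppresses a pure mains sinusoid by at least 20 dB", {
  t <- (0:511) / 128
  x <- matrix(rep(sin(2 * pi * 50 * t), 8), 8, byrow = TRUE,
              dimnames = list(c("I", "II", paste0("V", 1:6)), NULL))
  out <- preprocess_trace(ecg_record(x, fs = 128), target_fs = 128,
                          target_len = 512, notch_freq = 50)
  # independent RMS oracle, ignoring filter transients at the edges
  core <- 65:448
  rms_in <- sqrt(mean(x[1, core]^2))
  rms_out <- sqrt(mean(out$trace[1, core]^2))
  expect_lt(rms_out, 0.1 * rms_in)
})

test_that("resampling converts the sampling rate and preserves content", {
  t <- (0:999) / 500
  x <- sin(2 * pi * 7 * t)
  out <- preprocess_trace(mk_record(x, 500), target_fs = 400,
                          target_len = 1024, notch_freq = 50)
  expect_equal(out$fs, 400)
  nv <- attr(out, "n_valid")
  expect_equal(nv, 800)
  # dominant frequency still 7 Hz at the new rate (DFT oracle)
  sp <- abs(fft(out$trace[1, 1:nv]))
  f <- (which.max(sp[2:(nv / 2)])) * 400 / nv
  expect_equal(f, 7, tolerance = 0.2)
})

test_that("a notch at or above Nyquist is rejected", {
  x <- matrix(rnorm(8 * 256), 8,
              dimnames = list(c("I", "II", paste0("V", 1:6)), NULL))
  expect_error(preprocess_trace(ecg_record(x, fs = 100), target_fs = 100,
                                target_len = 256, notch_freq = 50),
               "Nyquist")
})

test_that("preprocessing is near-idempotent up to filter transients", {
  rec <- synthesize_ecg(4.5, effect = effect_profile("strong"),
                        fs = 128, duration = 3.9, seed = 12)
  p1 <- preprocess_trace(rec, target_fs = 128, target_len = 512)
  p2 <- preprocess_trace(p1, target_fs = 128, target_len = 512)
  core <- 33:480 # ignore edge transients
  expect_gt(cor(as.numeric(p1$trace[, core]), as.numeric(p2$trace[, core])),
            0.99)
})

test_that("cohort preprocessing records per-trace valid lengths", {
  co <- sample_cohort(analyte_profile("potassium"), 10, seed = 3)
  cp <- preprocess_cohort(co)
  expect_equal(dim(cp$traces)[2], 512)
  expect_true(all(cp$ecgs$n_valid == round(128 * 3.9)))
  expect_equal(cp$ecgs$fs, rep(128, nrow(cp$ecgs)))
  # padding tail is exactly zero
  expect_true(all(cp$traces[, 500:512, 1] == 0))
})
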