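test_that("cohort concentrations match the analyte's marginal moments", {
  a <- analyte_profile("potassium")
  co <- sample_cohort(a, 10000, ecgs_per_patient = 1, labs_per_patient = 1,
                      duration = 1, noise = noise_free(), seed = 42)
  m <- mean(co$patients$latent_concentration)
  s <- sd(co$patients$latent_concentration)
  expect_lt(abs(m - 3.99), 0.02)
  expect_lt(abs(s - 0.50), 0.02)
})

test_that("generation is a pure function of (config, seed)", {
  a <- analyte_profile("potassium")
  c1 <- sample_cohort(a, 40, seed = 9)
  c2 <- sample_cohort(a, 40, seed = 9)
  expect_identical(c1, c2)
  c3 <- sample_cohort(a, 40, seed = 10)
  expect_false(identical(c1$traces, c3$traces))
})

test_that("age-variance slope raises concentration spread in older deciles", {
  a <- analyte_profile("potassium")
  co <- sample_cohort(a, 20000, ecgs_per_patient = 1, labs_per_patient = 1,
                      duration = 1, noise = noise_free(),
                      age_variance_slope = 1.5, seed = 13)
  # brute-force group statistics oracle
  dec <- cut(co$patients$age,
             quantile(co$patients$age, probs = seq(0, 1, 0.1)),
             include.lowest = TRUE, labels = FALSE)
  sds <- tapply(co$patients$latent_concentration, dec, sd)
  expect_gt(sds[[10]], sds[[1]])
})

test_that("invalid generator configuration is rejected", {
  expect_error(analyte_spec("x", mean = 4, sd = -1), "sd")
  expect_error(count_dist(min = 0), "counts >= 1")
  expect_error(sample_cohort(analyte_profile("potassium"), 0), "n_patients")
  expect_error(noise_spec(baseline_wander_amp = -0.1), ">= 0")
})

test_that("null effect model makes the waveform independent of concentration", {
  eff <- effect_model(0, 0)
  r1 <- synthesize_ecg(3.0, effect = eff, noise = noise_free(), seed = 5)
  r2 <- synthesize_ecg(6.0, effect = eff, noise = noise_free(), seed = 5)
  expect_identical(r1$trace, r2$trace)
})

test_that("T-peak amplitude increases with concentration under a positive coefficient", {
  eff <- effect_model(t_amplitude_coeff = 0.45, reference_concentration = 4)
  amps <- vapply(c(3, 4, 5, 6), function(conc) {
    measure_t_amplitude(synthesize_ecg(conc, effect = eff,
                                       noise = noise_free(), seed = 21))
  }, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("repolarization interval lengthens with a calcium-like coefficient", {
  eff <- effect_model(repol_interval_coeff = 0.05, reference_concentration = 4)
  rec_lo <- synthesize_ecg(3, effect = eff, noise = noise_free(), seed = 3)
  rec_hi <- synthesize_ecg(5, effect = eff, noise = noise_free(), seed = 3)
  # T window annotations shift by coeff * delta-concentration
  shift <- attr(rec_hi, "beats")$t_window_start[1] -
    attr(rec_lo, "beats")$t_window_start[1]
  expect_equal(shift, 0.05 * 2, tolerance = 1e-9)
  expect_error(synthesize_ecg(6, effect = effect_model(0, -5)),
               "repolarization")
})

test_that("powerline noise concentrates spectral power at the mains frequency", {
  ns <- noise_spec(baseline_wander_amp = 0, powerline_amp = 0.5,
                   powerline_freq = 50, white_sd = 0)
  rec <- synthesize_ecg(4, effect = effect_model(0, 0), noise = ns,
                        fs = 128, duration = 4, seed = 17)
  # independent DFT oracle
  sp <- abs(fft(rec$trace["I", ]))
  freqs <- (seq_along(sp) - 1) * 128 / length(sp)
  bin50 <- which.min(abs(freqs - 50))
  neighbors <- sp[setdiff(seq(bin50 - 12, bin50 + 12), (bin50 - 2):(bin50 + 2))]
  expect_gt(sp[bin50], 20 * median(neighbors))
})

test_that("trace length and argument validation follow the contract", {
  rec <- synthesize_ecg(4, fs = 128, duration = 2.5, seed = 1)
  expect_equal(ncol(rec$trace), round(128 * 2.5))
  expect_equal(rownames(rec$trace), c("I", "II", paste0("V", 1:6)))
  expect_error(synthesize_ecg(4, fs = 50), "fs")
  expect_error(synthesize_ecg(4, heart_rate = 300), "heart_rate")
})
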