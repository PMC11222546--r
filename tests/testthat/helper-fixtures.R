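# Shared, lazily-built fixtures. Cohort generation and model training are
# the expensive steps, so fixtures are memoized across test files within a
# session. All sizes are the package's desk-scale study conditions: ~1300
# patients (~2000 ECGs) per cohort, the tiny backbone, and 20-30 epoch
# training budgets.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

fixture_strong_data <- function() {
  memo("strong_data", function() {
    co <- sample_cohort(analyte_profile("potassium"), 1300,
                        effect = effect_profile("strong"),
                        lab_noise_sd = 0.25, seed = 101)
    prepare_model_data(preprocess_cohort(co), seed = 202)
  })
}

fixture_null_data <- function() {
  memo("null_data", function() {
    co <- sample_cohort(analyte_profile("potassium"), 1300,
                        effect = effect_profile("null"),
                        lab_noise_sd = 0.25, seed = 103)
    prepare_model_data(preprocess_cohort(co), seed = 204)
  })
}

fixture_weak_data <- function() {
  memo("weak_data", function() {
    an <- analyte_profile("calcium")
    co <- sample_cohort(an, 1300,
                        effect = effect_profile("weak", reference = an$mean),
                        lab_noise_sd = 0.03, seed = 105)
    prepare_model_data(preprocess_cohort(co), seed = 206)
  })
}

fixture_direct_strong <- function() {
  memo("direct_strong", function() {
    train_direct(fixture_strong_data(), backbone_tiny(),
                 train_config(epochs = 20, seed = 11))
  })
}

fixture_ensemble_strong <- function() {
  memo("ensemble_strong", function() {
    train_ensemble(fixture_strong_data(), backbone_tiny(),
                   train_config(epochs = 30, seed = 31), n_members = 5)
  })
}

fixture_laplace_strong <- function() {
  memo("laplace_strong", function() {
    lapply(fixture_ensemble_strong()$members, fit_laplace,
           data = fixture_strong_data())
  })
}

# small quick dataset for mechanics tests (serialization, determinism, ...)
fixture_small_data <- function() {
  memo("small_data", function() {
    co <- sample_cohort(analyte_profile("potassium"), 150,
                        effect = effect_profile("strong"),
                        lab_noise_sd = 0.05, seed = 7)
    prepare_model_data(preprocess_cohort(co), seed = 8)
  })
}

fixture_direct_mini <- function() {
  memo("direct_mini", function() {
    train_direct(fixture_small_data(), backbone_tiny(),
                 train_config(epochs = 4, seed = 5))
  })
}

# fabricated linked_dataset around externally supplied arrays, for baseline
# construction oracles that need full control of the input-target map
make_fake_dataset <- function(x_train, y_train, x_val, y_val,
                              x_test, y_test) {
  norm <- fit_normalizer(y_train)
  part <- function(x, y) list(x = x, y = y,
                              n_valid = rep(dim(x)[2], dim(x)[3]))
  structure(list(train = part(x_train, y_train),
                 val = part(x_val, y_val),
                 random_test = part(x_test, y_test),
                 temporal_test = part(x_test, y_test),
                 norm = norm),
            class = "linked_dataset")
}
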