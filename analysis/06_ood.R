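# Distribution-shift protocols: additive Gaussian noise at SNR 10 and 1,
# and random masking of a quarter / half of each trace. Uses the ensemble
# trained by analysis/05_uncertainty.R.

source("analysis/00_common.R")

cp <- load_processed("strong_potassium")
d <- prepare_model_data(cp, seed = SPLIT_SEED)
art <- readRDS(file.path(RESULTS_DIR, "ensemble.rds"))

rep <- ood_report(
  art$ensemble, d$random_test$x, d$random_test$y,
  conditions = list(
    baseline = NULL,
    snr10 = list(kind = "gaussian_noise", snr = 10),
    snr1 = list(kind = "gaussian_noise", snr = 1),
    mask25 = list(kind = "masking", proportion = 0.25),
    mask50 = list(kind = "masking", proportion = 0.50)),
  posteriors = art$posteriors, seed = 9, n_valid = d$random_test$n_valid)
write_table(rep, "ood_report")
print(rep)
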