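# Probabilistic regression on the predictable cohort: a 5-member Gaussian
# ensemble with last-layer Laplace posteriors, evaluated by sparsification,
# central-interval calibration and uncertainty-error correlation.

source("analysis/00_common.R")

cp <- load_processed("strong_potassium")
d <- prepare_model_data(cp, seed = SPLIT_SEED)

ens <- train_ensemble(d, backbone_tiny(),
                      train_config(epochs = 30, seed = 31), n_members = 5)
post <- lapply(ens$members, fit_laplace, data = d)
saveRDS(list(ensemble = ens, posteriors = post),
        file.path(RESULTS_DIR, "ensemble.rds"))

x <- d$random_test$x; y <- d$random_test$y
ue <- uncertainty_estimates(ens, x, post)
err <- abs(ue$mean_prediction - y)

summary_row <- data.frame(
  mae = mean(err),
  aleatoric_sd = mean(sqrt(ue$aleatoric_gaussian)),
  epistemic_ensemble_sd = mean(sqrt(ue$epistemic_ensemble)),
  epistemic_laplace_sd = mean(sqrt(ue$epistemic_laplace)))
write_table(summary_row, "uncertainty_summary")
print(summary_row)

sp_rows <- list()
for (kind in c("aleatoric_gaussian", "epistemic_ensemble",
               "epistemic_laplace")) {
  sp <- sparsification(err, ue[[kind]])
  sp_rows[[kind]] <- data.frame(uncertainty = kind, sp)
}
sp_rows$oracle <- data.frame(uncertainty = "oracle",
                             sparsification(err, err))
write_table(do.call(rbind, sp_rows), "sparsification")

total_var <- ue$aleatoric_gaussian + ue$epistemic_ensemble
cal <- calibration_curve(ue$mean_prediction, total_var, y)
write_table(cal, "calibration")
print(cal)

corr <- uncertainty_error_correlation(
  list(aleatoric_gaussian = ue$aleatoric_gaussian,
       epistemic_ensemble = ue$epistemic_ensemble,
       epistemic_laplace = ue$epistemic_laplace),
  (ue$mean_prediction - y)^2)
write_table(corr, "uncertainty_error_correlation")
print(corr)
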