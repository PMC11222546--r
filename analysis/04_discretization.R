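# The regression -> classification spectrum: AUmROC for classification and
# ordinal models as the number of classes k grows, the hypo/hyper binary
# AUROC pair at k = 2, and the error cost of mapping classes back to
# concentrations.

source("analysis/00_common.R")

cp <- load_processed("strong_potassium")
d <- prepare_model_data(cp, seed = SPLIT_SEED)

# AUmROC vs k over 5 seeds per formulation (subset the training ECGs so the
# sweep stays desk-sized)
set.seed(1)
keep <- sample(length(d$train$y), min(500, length(d$train$y)))
ds <- d
ds$train$x <- d$train$x[, , keep, drop = FALSE]
ds$train$y <- d$train$y[keep]
tab <- spectrum_experiment(ds, k_list = c(3, 5, 7), n_seeds = 5,
                           epochs = 10, base_seed = 77)
write_table(tab, "spectrum_runs")
agg <- aggregate(aumroc ~ k + formulation, tab,
                 function(v) c(mean = mean(v), sd = sd(v)))
agg <- do.call(data.frame, agg)
names(agg) <- c("k", "formulation", "aumroc_mean", "aumroc_sd")
write_table(agg, "spectrum_aumroc")
print(agg)

# k = 2: hypo/hyper binary pair scored from a Gaussian model's predictive
# distribution (probability mass below/above the clinical bounds)
g <- train_gaussian(d, backbone_tiny(), train_config(epochs = 20, seed = 13))
pr <- predict(g, d$random_test$x)
tasks <- build_binary_tasks(analyte_profile("potassium"))
pair <- binary_auroc_pair(
  hypo_scores = pnorm(tasks$hypo_bound, pr$mean, pr$sd),
  hyper_scores = 1 - pnorm(tasks$hyper_bound, pr$mean, pr$sd),
  targets = d$random_test$y, tasks = tasks)
write_table(data.frame(task = c("hypo", "hyper", "average"),
                       auroc = c(pair$hypo_auroc, pair$hyper_auroc,
                                 pair$average)),
            "binary_auroc")
message(sprintf("hypo %.3f / hyper %.3f AUROC", pair$hypo_auroc,
                pair$hyper_auroc))

# class-to-continuous back-mapping cost vs direct regression
scheme5 <- build_scheme(5, d$train$y)
cls_model <- train_classifier(d, scheme5, backbone_tiny(),
                              train_config(epochs = 15, seed = 14))
pc <- predict(cls_model, d$random_test$x)
direct <- train_direct(d, backbone_tiny(), train_config(epochs = 20, seed = 11))
mae_direct <- mean(abs(predict(direct, d$random_test$x) - d$random_test$y))
mae_class <- mean(abs(pc$value - d$random_test$y))
write_table(data.frame(model = c("direct", "class5_backmapped"),
                       mae = c(mae_direct, mae_class)),
            "backmapping_mae")
message(sprintf("MAE: direct %.3f, 5-class back-mapped %.3f",
                mae_direct, mae_class))
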