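# Shared settings for the analysis scripts. Desk-scale study conditions:
# ~1300 patients (~2000 ECGs) per cohort, 128 Hz / 512-sample traces, the
# tiny residual backbone. Every script can be run standalone from the
# repository root with: Rscript analysis/0X_<name>.R

library(ecglyte)

RESULTS_DIR <- "results"
COHORT_DIR <- file.path(RESULTS_DIR, "cohorts")
dir.create(COHORT_DIR, recursive = TRUE, showWarnings = FALSE)

N_PATIENTS <- 1300
MASTER_SEED <- 101
SPLIT_SEED <- 202

# lab_noise_sd emulates effective label noise (assay error plus biological
# drift between ECG and blood draw): 0.25 mmol/l for potassium, 0.03 for the
# tightly regulated calcium
cohort_specs <- list(
  strong_potassium = list(analyte = "potassium", effect = "strong",
                          lab_noise_sd = 0.25, seed = MASTER_SEED),
  weak_calcium = list(analyte = "calcium", effect = "weak",
                      lab_noise_sd = 0.03, seed = MASTER_SEED + 4),
  null_potassium = list(analyte = "potassium", effect = "null",
                        lab_noise_sd = 0.25, seed = MASTER_SEED + 2)
)

# cohorts are simulated once by 01_simulate.R and reread by later scripts
load_processed <- function(name) {
  path <- file.path(COHORT_DIR, paste0(name, "_processed"))
  if (!dir.exists(path)) {
    stop("run analysis/01_simulate.R and analysis/02_preprocess.R first")
  }
  read_cohort(path)
}

write_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE)
  message("wrote ", path)
}
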