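# Preprocess every cohort (high-pass, mains notch, zero-padding to the
# 512-sample desk format) and report the dataset-construction outcome:
# linking yield within the +/-60 min window and the patient-level
# random/temporal split sizes.

source("analysis/00_common.R")

rows <- list()
for (name in names(cohort_specs)) {
  co <- read_cohort(file.path(COHORT_DIR, name))
  cp <- preprocess_cohort(co)
  write_cohort(cp, file.path(COHORT_DIR, paste0(name, "_processed")))

  linked <- link_ecg_lab(cp$ecgs, cp$labs)
  sp <- split_patients(cp$patients, cp$ecgs, seed = SPLIT_SEED)
  parts <- select_eval_ecgs(linked, cp$ecgs, sp)
  jsonlite::write_json(
    list(cutoff = format(sp$cutoff_date), seed = sp$seed,
         patients = sp$patients, removed_ecgs = sp$removed_ecg_ids),
    file.path(COHORT_DIR, paste0(name, "_splits.json")), auto_unbox = TRUE)

  rows[[name]] <- data.frame(
    cohort = name,
    ecgs_total = nrow(cp$ecgs),
    ecgs_linked = nrow(linked),
    ecgs_dropped_no_lab = attr(linked, "n_dropped"),
    ecgs_removed_post_cutoff = length(sp$removed_ecg_ids),
    train = nrow(parts$train), val = nrow(parts$val),
    random_test = nrow(parts$random_test),
    temporal_test = nrow(parts$temporal_test))
  message(sprintf("%s: %d/%d ECGs linked; train/val/rt/tt = %d/%d/%d/%d",
                  name, nrow(linked), nrow(cp$ecgs), nrow(parts$train),
                  nrow(parts$val), nrow(parts$random_test),
                  nrow(parts$temporal_test)))
}
write_table(do.call(rbind, rows), "dataset_summary")
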