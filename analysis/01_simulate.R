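# Simulate the three study cohorts: a potassium-like analyte with a strong
# T-wave-amplitude effect (the predictable case), a calcium-like analyte
# whose repolarization effect is far below the noise floor (the
# unpredictable case), and a null cohort with no electrolyte-to-waveform
# relationship at all (the sanity floor). Each cohort is written to the
# directory container so later stages consume exactly what a user-supplied
# dataset would look like.

source("analysis/00_common.R")

summary_rows <- list()
for (name in names(cohort_specs)) {
  spec <- cohort_specs[[name]]
  an <- analyte_profile(spec$analyte)
  co <- sample_cohort(an, N_PATIENTS,
                      effect = effect_profile(spec$effect,
                                              reference = an$mean),
                      lab_noise_sd = spec$lab_noise_sd, seed = spec$seed)
  write_cohort(co, file.path(COHORT_DIR, name))
  summary_rows[[name]] <- data.frame(
    cohort = name, analyte = spec$analyte, effect = spec$effect,
    patients = nrow(co$patients), ecgs = nrow(co$ecgs),
    labs = nrow(co$labs),
    conc_mean = mean(co$patients$latent_concentration),
    conc_sd = sd(co$patients$latent_concentration),
    pct_male = 100 * mean(co$patients$sex == "male"),
    age_mean = mean(co$patients$age), age_sd = sd(co$patients$age))
  message(sprintf("%s: %d patients, %d ECGs, conc %.2f (%.2f)",
                  name, nrow(co$patients), nrow(co$ecgs),
                  mean(co$patients$latent_concentration),
                  sd(co$patients$latent_concentration)))
}
write_table(do.call(rbind, summary_rows), "cohort_summary")
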