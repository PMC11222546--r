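#' Analyte specification
#'
#' Describes the marginal concentration distribution of one blood analyte and
#' its clinically abnormal (hypo/hyper) decision bounds. The built-in profiles
#' (see [analyte_profile()]) carry the population moments of a large Swedish
#' emergency-department cohort: e.g. potassium mean 3.99 mmol/l, sd 0.50.
#'
#' @param name analyte identifier (e.g. "potassium")
#' @param mean,sd marginal concentration mean and standard deviation; `sd > 0`
#' @param unit_label unit string, e.g. "mmol/l"
#' @param hypo_bound,hyper_bound clinical low/high decision bounds with
#'   `hypo_bound < mean < hyper_bound`
#' @param distribution "gaussian" (truncated to positive values) or
#'   "lognormal"; log-normal suits analytes such as creatinine whose sd is of
#'   the order of the mean, where a positive-truncated Gaussian would be badly
#'   distorted
#' @return an object of class `analyte_spec`
#' @export
analyte_spec <- function(name, mean, sd, unit_label = "mmol/l",
                         hypo_bound = NULL, hyper_bound = NULL,
                         distribution = c("gaussian", "lognormal")) {
  distribution <- match.arg(distribution)
  stopifnot_scalar_pos(sd, "sd")
  stopifnot_scalar_pos(mean, "mean")
  hypo_bound <- hypo_bound %||% (mean - 2 * sd)
  hyper_bound <- hyper_bound %||% (mean + 2 * sd)
  if (!(hypo_bound < mean && mean < hyper_bound)) {
    stop("need hypo_bound < mean < hyper_bound", call. = FALSE)
  }
  structure(
    list(name = as.character(name), mean = mean, sd = sd,
         unit_label = unit_label, hypo_bound = hypo_bound,
         hyper_bound = hyper_bound, distribution = distribution),
    class = "analyte_spec"
  )
}

#' Built-in analyte profiles
#'
#' Population moments and abnormality bounds for the four analytes studied in
#' large ECG/electrolyte cohorts. Potassium and calcium bounds are standard
#' hypo/hyper definitions (3.5/5.5 and 2.0/2.75 mmol/l); sodium uses 130/150
#' mmol/l. Creatinine has no widely agreed pair of bounds in this framing, so
#' its profile defaults to mean +/- 2 sd and is drawn log-normally (its sd,
#' 71.0 at mean 90.55 umol/l, would force heavy truncation on a Gaussian).
#'
#' @param name one of "potassium", "calcium", "sodium", "creatinine"
#' @return an [analyte_spec()]
#' @export
#' @examples
#' analyte_profile("potassium")$hyper_bound  # 5.5
analyte_profile <- function(name = c("potassium", "calcium", "sodium", "creatinine")) {
  name <- match.arg(name)
  switch(name,
    potassium = analyte_spec("potassium", mean = 3.99, sd = 0.50,
                             unit_label = "mmol/l",
                             hypo_bound = 3.5, hyper_bound = 5.5),
    calcium = analyte_spec("calcium", mean = 2.29, sd = 0.13,
                           unit_label = "mmol/l",
                           hypo_bound = 2.0, hyper_bound = 2.75),
    sodium = analyte_spec("sodium", mean = 138.93, sd = 3.82,
                          unit_label = "mmol/l",
                          hypo_bound = 130, hyper_bound = 150),
    creatinine = analyte_spec("creatinine", mean = 90.55, sd = 71.00,
                              unit_label = "umol/l",
                              distribution = "lognormal")
  )
}

#' Electrolyte-to-morphology effect model
#'
#' Encodes how the latent analyte concentration deforms the synthetic beat:
#' the T-wave amplitude is scaled by `1 + t_amplitude_coeff * (c - reference)`
#' (potassium chiefly modulates T-wave morphology) and the S-to-T-onset
#' repolarization interval is lengthened by
#' `repol_interval_coeff * (c - reference)` seconds (calcium chiefly modulates
#' the QT duration). With both coefficients zero the waveform is independent
#' of concentration, which is the null cohort used for sanity checks.
#'
#' @param t_amplitude_coeff dimensionless per unit concentration
#' @param repol_interval_coeff seconds per unit concentration
#' @param reference_concentration concentration at which the beat equals the
#'   unmodified template
#' @return an object of class `effect_model`
#' @export
effect_model <- function(t_amplitude_coeff = 0,
                         repol_interval_coeff = 0,
                         reference_concentration = 4) {
  stopifnot(is.numeric(t_amplitude_coeff), is.numeric(repol_interval_coeff))
  structure(
    list(t_amplitude_coeff = t_amplitude_coeff,
         repol_interval_coeff = repol_interval_coeff,
         reference_concentration = reference_concentration),
    class = "effect_model"
  )
}

#' Canned effect profiles
#'
#' "strong" produces a clearly learnable T-amplitude relationship (the
#' potassium-like regime), "weak" a sub-sample repolarization shift that is
#' practically invisible at typical noise levels (the calcium-like regime),
#' and "null" no relationship at all.
#'
#' @param profile one of "strong", "weak", "null"
#' @param reference concentration anchoring the unmodified template
#' @export
effect_profile <- function(profile = c("strong", "weak", "null"), reference = 4) {
  profile <- match.arg(profile)
  switch(profile,
    strong = effect_model(t_amplitude_coeff = 0.45, repol_interval_coeff = 0,
                          reference_concentration = reference),
    weak = effect_model(t_amplitude_coeff = 0, repol_interval_coeff = 0.010,
                        reference_concentration = reference),
    null = effect_model(0, 0, reference_concentration = reference)
  )
}

#' Additive noise specification for synthetic ECGs
#'
#' Baseline wander (slow sinusoidal drift), powerline interference
#' (50 Hz by default, the European mains frequency) and white sensor noise.
#' These are the components the preprocessing high-pass and notch filters are
#' designed to remove. All amplitudes in millivolt.
#'
#' @param baseline_wander_amp amplitude of the ~0.25 Hz drift component
#' @param powerline_amp amplitude of the mains sinusoid
#' @param powerline_freq mains frequency in Hz
#' @param white_sd standard deviation of white Gaussian noise
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(baseline_wander_amp = 0.05, powerline_amp = 0.02,
                       powerline_freq = 50, white_sd = 0.02) {
  amps <- c(baseline_wander_amp, powerline_amp, white_sd)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("noise amplitudes must be finite and >= 0", call. = FALSE)
  }
  stopifnot_scalar_pos(powerline_freq, "powerline_freq")
  structure(
    list(baseline_wander_amp = baseline_wander_amp,
         powerline_amp = powerline_amp,
         powerline_freq = powerline_freq,
         white_sd = white_sd),
    class = "noise_spec"
  )
}

#' Noise-free specification (all amplitudes zero)
#' @export
noise_free <- function() noise_spec(0, 0, 50, 0)
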