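#' Count-distribution specification
#'
#' Per-patient counts of ECGs or labs are drawn as `min + rpois(lambda)`,
#' guaranteeing at least `min` of each.
#'
#' @param lambda Poisson rate of the extra counts
#' @param min minimum count, `>= 1`
#' @export
count_dist <- function(lambda = 0.7, min = 1) {
  if (min < 1) stop("count distributions must yield counts >= 1", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  structure(list(lambda = lambda, min = as.integer(min)), class = "count_dist")
}

draw_counts <- function(spec, n) {
  if (is.numeric(spec) && length(spec) == 1L) {
    if (spec < 1) stop("count must be >= 1", call. = FALSE)
    return(rep(as.integer(spec), n))
  }
  spec$min + stats::rpois(n, spec$lambda)
}

COHORT_SCHEMA_VERSION <- "1"

#' Construct a cohort object
#'
#' @param patients data.frame: patient_id, age, sex, admission_date,
#'   latent_concentration
#' @param ecgs data.frame: ecg_id, patient_id, acquisition_time, fs, trace_row
#' @param labs data.frame: lab_id, patient_id, analyte, value, unit, time
#' @param traces numeric array `leads x samples x n_ecgs` (float32-snapped)
#' @param config generator configuration + seed (provenance)
#' @return object of class `ecg_cohort`
#' @export
ecg_cohort <- function(patients, ecgs, labs, traces, config = list()) {
  stopifnot(all(ecgs$patient_id %in% patients$patient_id),
            all(labs$patient_id %in% patients$patient_id))
  if (nrow(ecgs) != dim(traces)[3]) {
    stop("trace array depth must equal the number of ECG rows", call. = FALSE)
  }
  structure(
    list(patients = patients, ecgs = ecgs, labs = labs, traces = traces,
         config = config, schema_version = COHORT_SCHEMA_VERSION),
    class = "ecg_cohort"
  )
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf("<ecg_cohort> %d patients, %d ECGs (%d leads x %d samples), %d labs\n",
              nrow(x$patients), nrow(x$ecgs),
              dim(x$traces)[1], dim(x$traces)[2], nrow(x$labs)))
  invisible(x)
}

#' Sample a synthetic patient cohort with linked ECGs and lab values
#'
#' Emulates the statistical structure of an emergency-department
#' ECG/electrolyte cohort: patient ages are drawn from a truncated normal
#' (mean 61.3, sd 19.6 years, range 18-100), sexes are near-balanced (49.4%
#' male), and admission dates are uniform over the study window (2009-2017 by
#' default) so a temporal split at 2017-01-01 is exercisable. Each patient
#' carries one latent analyte concentration drawn so the cohort's marginal
#' mean/sd match the [analyte_spec()]; with `age_variance_slope > 0` the
#' conditional concentration sd increases linearly with age while the
#' marginal sd is rescaled to stay at the specified value. Lab values are the
#' latent concentration plus i.i.d. Gaussian measurement noise
#' (`lab_noise_sd`). ECG and lab timestamps are offset uniformly within
#' `+/- offset_window_minutes` of one encounter time, so pairs both inside
#' and outside a +/-60 min linking window arise.
#'
#' @param analyte an [analyte_spec()]
#' @param n_patients number of patients, `>= 1`
#' @param ecgs_per_patient,labs_per_patient a [count_dist()] or a fixed count
#' @param age_variance_slope relative increase of the conditional
#'   concentration sd from age 18 to age 100 (0 = homoscedastic in age)
#' @param effect an [effect_model()] mapping concentration to morphology
#' @param noise a [noise_spec()]
#' @param lab_noise_sd sd of the lab measurement error, same units as the
#'   analyte
#' @param fs,duration sampling rate (Hz) and trace length (seconds)
#' @param heart_rate_range per-ECG heart rate drawn uniformly from this range
#' @param gain_log_sd sd of the per-ECG log-normal amplitude gain
#' @param date_range character vector of two dates bounding admissions
#' @param offset_window_minutes half-width of the timestamp offset window
#' @param seed integer seed; the cohort is a pure function of (config, seed)
#' @return an [ecg_cohort()]
#' @export
sample_cohort <- function(analyte, n_patients,
                          ecgs_per_patient = count_dist(0.5),
                          labs_per_patient = count_dist(0.7),
                          age_variance_slope = 0,
                          effect = effect_model(reference_concentration = analyte$mean),
                          noise = noise_spec(),
                          lab_noise_sd = 0,
                          fs = 128, duration = 3.9,
                          heart_rate_range = c(55, 95),
                          gain_log_sd = 0.05,
                          date_range = c("2009-01-01", "2017-12-31"),
                          offset_window_minutes = 90,
                          seed = 1) {
  if (!inherits(analyte, "analyte_spec")) stop("need an analyte_spec", call. = FALSE)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (lab_noise_sd < 0) stop("lab_noise_sd must be >= 0", call. = FALSE)

  config <- list(
    analyte = unclass(analyte), n_patients = n_patients,
    ecgs_per_patient = unclass(ecgs_per_patient),
    labs_per_patient = unclass(labs_per_patient),
    age_variance_slope = age_variance_slope,
    effect = unclass(effect), noise = unclass(noise),
    lab_noise_sd = lab_noise_sd, fs = fs, duration = duration,
    heart_rate_range = heart_rate_range, gain_log_sd = gain_log_sd,
    date_range = date_range,
    offset_window_minutes = offset_window_minutes, seed = seed
  )

  with_local_seed(seed, {
    # --- patients -----------------------------------------------------------
    age <- truncnorm_draw(n_patients, 61.26, 19.61, 18, 100)
    sex <- ifelse(stats::runif(n_patients) < 0.4938, "male", "female")
    d0 <- as.Date(date_range[1]); d1 <- as.Date(date_range[2])
    admission <- d0 + floor(stats::runif(n_patients, 0, as.numeric(d1 - d0) + 1))

    conc <- draw_concentrations(analyte, age, age_variance_slope)

    patients <- data.frame(
      patient_id = sprintf("P%05d", seq_len(n_patients)),
      age = age, sex = sex, admission_date = admission,
      latent_concentration = conc,
      stringsAsFactors = FALSE
    )

    # one encounter time per patient, on the admission day
    encounter <- as.POSIXct(admission, tz = "UTC") +
      round(stats::runif(n_patients, 8 * 3600, 20 * 3600))

    # --- labs ---------------------------------------------------------------
    n_labs <- draw_counts(labs_per_patient, n_patients)
    lab_pat <- rep(seq_len(n_patients), n_labs)
    lab_off <- round(stats::runif(sum(n_labs), -offset_window_minutes * 60,
                                  offset_window_minutes * 60))
    lab_val <- conc[lab_pat] +
      if (lab_noise_sd > 0) stats::rnorm(sum(n_labs), 0, lab_noise_sd) else 0
    lab_val <- pmax(lab_val, 0.01)
    labs <- data.frame(
      lab_id = sprintf("L%06d", seq_len(sum(n_labs))),
      patient_id = patients$patient_id[lab_pat],
      analyte = analyte$name, value = lab_val, unit = analyte$unit_label,
      time = encounter[lab_pat] + lab_off,
      stringsAsFactors = FALSE
    )

    # --- ECGs ---------------------------------------------------------------
    n_ecgs <- draw_counts(ecgs_per_patient, n_patients)
    ecg_pat <- rep(seq_len(n_patients), n_ecgs)
    m <- sum(n_ecgs)
    ecg_off <- round(stats::runif(m, -offset_window_minutes * 60,
                                  offset_window_minutes * 60))
    hr <- stats::runif(m, heart_rate_range[1], heart_rate_range[2])
    gain <- exp(stats::rnorm(m, 0, gain_log_sd))
    ecg_seeds <- child_seed(seed, seq_len(m))

    n_samp <- round(fs * duration)
    traces <- array(0, dim = c(length(LEADS8), n_samp, m),
                    dimnames = list(LEADS8, NULL, NULL))
    for (i in seq_len(m)) {
      rec <- synthesize_ecg(conc[ecg_pat[i]], effect = effect, noise = noise,
                            heart_rate = hr[i], fs = fs, duration = duration,
                            seed = ecg_seeds[i], gain = gain[i])
      traces[, , i] <- rec$trace
    }
    traces <- as_float32(traces)
    dimnames(traces) <- list(LEADS8, NULL, NULL)

    ecgs <- data.frame(
      ecg_id = sprintf("E%06d", seq_len(m)),
      patient_id = patients$patient_id[ecg_pat],
      acquisition_time = encounter[ecg_pat] + ecg_off,
      fs = fs, heart_rate = hr, gain = gain,
      trace_row = seq_len(m),
      stringsAsFactors = FALSE
    )

    ecg_cohort(patients, ecgs, labs, traces, config)
  })
}

# exact truncated-normal draws via inverse-CDF (no rejection loops)
truncnorm_draw <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm((lo - mean) / sd)
  phi <- stats::pnorm((hi - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, plo, phi))
}

# Per-patient latent concentrations. With a positive age-variance slope the
# conditional sd grows linearly in age; dividing by the root-mean-square of
# the growth factors keeps the marginal sd at the specified value.
draw_concentrations <- function(analyte, age, slope) {
  n <- length(age)
  g <- 1 + slope * (age - 18) / 82
  g <- g / sqrt(mean(g^2))
  if (analyte$distribution == "lognormal") {
    sdlog <- sqrt(log(1 + (analyte$sd / analyte$mean)^2))
    meanlog <- log(analyte$mean) - sdlog^2 / 2
    exp(meanlog + sdlog * g * stats::rnorm(n))
  } else {
    z <- truncnorm_draw(n, 0, 1, (0.01 - analyte$mean) / analyte$sd, Inf)
    analyte$mean + analyte$sd * g * z
  }
}
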