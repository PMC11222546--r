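#' @keywords internal
LEADS8 <- c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")

#' @keywords internal
LEADS12 <- c("I", "II", "III", "aVR", "aVL", "aVF",
             "V1", "V2", "V3", "V4", "V5", "V6")

# Per-lead wave amplitude map (millivolt) for the Gaussian-wavelet beat
# template. Rows: the 8 independent leads; columns: P, Q, R, S, T.
# Values are stylized but give V-lead progression and limb-lead proportions
# in the right ballpark for a normal adult ECG.
beat_amplitude_map <- function() {
  m <- rbind(
    I  = c(0.08, -0.05, 0.70, -0.15, 0.20),
    II = c(0.12, -0.08, 1.00, -0.20, 0.30),
    V1 = c(0.05,  0.00, 0.30, -0.70, 0.10),
    V2 = c(0.06,  0.00, 0.60, -0.80, 0.35),
    V3 = c(0.07, -0.02, 0.90, -0.50, 0.40),
    V4 = c(0.08, -0.05, 1.20, -0.30, 0.35),
    V5 = c(0.08, -0.08, 1.10, -0.15, 0.30),
    V6 = c(0.07, -0.06, 0.90, -0.10, 0.25)
  )
  colnames(m) <- c("P", "Q", "R", "S", "T")
  m
}

# Wave timing relative to the R peak (seconds): centers and Gaussian widths.
# The S-to-T timing is parameterized through `repol_base` so the effect model
# can lengthen/shorten the repolarization interval.
beat_timing <- function() {
  list(
    center = c(P = -0.17, Q = -0.035, R = 0, S = 0.035),
    width = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.070),
    repol_base = 0.25 # S center to T center, seconds, at the reference concentration
  )
}

#' Construct an ECG record
#'
#' @param trace leads x samples numeric matrix (millivolt), rownames = lead labels
#' @param fs sampling rate in Hz
#' @param ecg_id,patient_id identifiers
#' @param acquisition_time POSIXct acquisition timestamp
#' @return object of class `ecg_record`
#' @export
ecg_record <- function(trace, fs, ecg_id = NA_character_,
                       patient_id = NA_character_,
                       acquisition_time = as.POSIXct(NA)) {
  stopifnot(is.matrix(trace), ncol(trace) >= 1, fs > 0)
  if (is.null(rownames(trace))) {
    stop("trace must carry lead labels as rownames", call. = FALSE)
  }
  structure(
    list(ecg_id = ecg_id, patient_id = patient_id,
         acquisition_time = acquisition_time, fs = fs,
         trace = trace, lead_labels = rownames(trace)),
    class = "ecg_record"
  )
}

#' Synthesize one 8-lead ECG trace
#'
#' Builds a quasi-periodic beat train as a sum of Gaussian wavelets per lead
#' (P, Q, R, S, T components with a fixed per-lead amplitude map), modulated
#' by the analyte concentration through [effect_model()]: the T amplitude is
#' scaled by `1 + t_amplitude_coeff * (c - reference)` and the S-to-T
#' repolarization interval is lengthened by
#' `repol_interval_coeff * (c - reference)` seconds. Baseline wander,
#' powerline interference and white noise are added per [noise_spec()].
#' With all effect coefficients and noise amplitudes zero, the output is
#' independent of `concentration`.
#'
#' The returned record carries a `beats` attribute annotating, per beat, the
#' R-peak time and the T-wave search window (seconds), used by measurement
#' oracles.
#'
#' @param concentration latent analyte concentration driving the morphology
#' @param effect an [effect_model()]
#' @param noise a [noise_spec()]
#' @param heart_rate beats per minute, in `[30, 220]`
#' @param fs sampling rate (Hz), `>= 100`
#' @param duration trace length in seconds
#' @param seed integer seed (beat jitter, phase, noise)
#' @param gain multiplicative per-recording amplitude factor (electrode
#'   placement nuisance); default 1
#' @param rr_jitter_sd per-beat RR jitter as a fraction of the RR interval
#' @return an [ecg_record()] with an 8-lead trace of `round(fs * duration)`
#'   samples
#' @export
synthesize_ecg <- function(concentration, effect = effect_model(),
                           noise = noise_spec(), heart_rate = 70,
                           fs = 100, duration = 5, seed = 1, gain = 1,
                           rr_jitter_sd = 0.02) {
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  stopifnot_scalar_pos(duration, "duration")
  if (heart_rate < 30 || heart_rate > 220) {
    stop("heart_rate must lie in [30, 220] bpm", call. = FALSE)
  }
  timing <- beat_timing()
  dc <- concentration - effect$reference_concentration
  repol <- timing$repol_base + effect$repol_interval_coeff * dc
  if (repol <= 0) {
    stop("effect model produces a non-positive repolarization interval",
         call. = FALSE)
  }
  t_mult <- 1 + effect$t_amplitude_coeff * dc

  n <- round(fs * duration)
  tt <- (seq_len(n) - 1) / fs
  rr <- 60 / heart_rate

  with_local_seed(seed, {
    phase <- stats::runif(1, 0, rr)
    n_beats <- ceiling((duration + 1) / rr) + 1L
    jitter <- stats::rnorm(n_beats, 0, rr_jitter_sd * rr)
    r_times <- phase + (seq_len(n_beats) - 1) * rr + jitter

    amp <- beat_amplitude_map()
    amp[, "T"] <- amp[, "T"] * t_mult
    centers <- c(timing$center, T = timing$center[["S"]] + repol)
    widths <- timing$width

    # one Gaussian wavelet per (wave, beat), shared across leads
    waves <- colnames(amp)
    G <- matrix(0, n, length(waves))
    for (w in seq_along(waves)) {
      cw <- centers[[waves[w]]]
      sw <- widths[[waves[w]]]
      for (b in seq_len(n_beats)) {
        mu <- r_times[b] + cw
        if (mu > -0.3 && mu < duration + 0.3) {
          G[, w] <- G[, w] + exp(-((tt - mu)^2) / (2 * sw^2))
        }
      }
    }
    trace <- t(G %*% t(amp)) # leads x samples

    if (noise$baseline_wander_amp > 0) {
      f_bw <- stats::runif(1, 0.15, 0.35)
      ph_bw <- stats::runif(nrow(trace), 0, 2 * pi)
      for (l in seq_len(nrow(trace))) {
        trace[l, ] <- trace[l, ] +
          noise$baseline_wander_amp * sin(2 * pi * f_bw * tt + ph_bw[l])
      }
    }
    if (noise$powerline_amp > 0) {
      ph_pl <- stats::runif(1, 0, 2 * pi)
      pl <- noise$powerline_amp * sin(2 * pi * noise$powerline_freq * tt + ph_pl)
      trace <- sweep(trace, 2, pl, "+")
    }
    if (noise$white_sd > 0) {
      trace <- trace + matrix(stats::rnorm(length(trace), 0, noise$white_sd),
                              nrow(trace))
    }
    trace <- trace * gain
    rownames(trace) <- LEADS8

    rec <- ecg_record(trace, fs = fs)
    t_center <- r_times + centers[["T"]]
    attr(rec, "beats") <- data.frame(
      r_time = r_times,
      t_window_start = t_center - 2 * widths[["T"]],
      t_window_end = t_center + 2 * widths[["T"]]
    )
    rec
  })
}

#' Measure the T-peak amplitude of a synthetic record
#'
#' Maximum absolute amplitude of a lead inside the annotated T windows;
#' a measurement oracle for effect-recovery checks, independent of any model.
#'
#' @param record an [ecg_record()] produced by [synthesize_ecg()]
#' @param lead lead label to measure (default "V4")
#' @return mean over fully-contained T windows of the in-window peak value
#' @export
measure_t_amplitude <- function(record, lead = "V4") {
  beats <- attr(record, "beats")
  if (is.null(beats)) stop("record carries no beat annotations", call. = FALSE)
  x <- record$trace[lead, ]
  n <- length(x)
  tt <- (seq_len(n) - 1) / record$fs
  peaks <- c()
  for (b in seq_len(nrow(beats))) {
    idx <- which(tt >= beats$t_window_start[b] & tt <= beats$t_window_end[b])
    if (length(idx) > 0 &&
        beats$t_window_start[b] >= 0 &&
        beats$t_window_end[b] <= tt[n]) {
      peaks <- c(peaks, max(x[idx]))
    }
  }
  if (length(peaks) == 0) return(NA_real_)
  mean(peaks)
}
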