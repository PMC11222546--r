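#' Preprocess one ECG record
#'
#' Reproduces the standard preparation for waveform models: polyphase
#' resampling to `target_fs`, a zero-phase Butterworth high-pass to remove
#' offsets and baseline drift, a zero-phase notch (narrow band-stop) at the
#' mains frequency, and zero-padding at the end to `target_len` samples.
#' The defaults (400 Hz, 4096 samples) fit standard 10-second recordings;
#' desk-scale experiments in this package use 128 Hz / 512 samples.
#'
#' @param record an [ecg_record()]
#' @param target_fs output sampling rate (Hz)
#' @param target_len output length in samples; traces longer than this after
#'   resampling raise an error
#' @param highpass_cutoff high-pass corner frequency (Hz); conventional ECG
#'   baseline cutoff 0.5 Hz
#' @param notch_freq mains frequency to suppress (Hz); must lie below the
#'   output Nyquist frequency
#' @param notch_q notch quality factor (centre frequency / stop-band width)
#' @return an [ecg_record()] at `target_fs` with exactly `target_len` samples
#'   and an `n_valid` attribute giving the number of non-padded samples
#' @export
preprocess_trace <- function(record, target_fs = 400, target_len = 4096,
                             highpass_cutoff = 0.5, notch_freq = 50,
                             notch_q = 30) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$trace
  if (ncol(x) < 1) stop("record has no samples", call. = FALSE)

  if (record$fs != target_fs) {
    pq <- rational_ratio(target_fs, record$fs)
    x <- t(apply(x, 1, function(row) signal::resample(row, pq[1], pq[2])))
  }
  if (ncol(x) > target_len) {
    stop(sprintf("trace too long: %d samples after resampling exceed target_len %d",
                 ncol(x), target_len), call. = FALSE)
  }

  nyq <- target_fs / 2
  hp <- signal::butter(2, highpass_cutoff / nyq, type = "high")
  if (notch_freq >= nyq) {
    stop("notch_freq must be below the output Nyquist frequency", call. = FALSE)
  }
  bw <- notch_freq / notch_q
  ns <- signal::butter(2, c(notch_freq - bw / 2, notch_freq + bw / 2) / nyq,
                       type = "stop")
  # explicit demeaning first: removes the DC component exactly and keeps the
  # zero-phase filters free of large edge transients on offset traces
  x <- x - rowMeans(x)
  for (l in seq_len(nrow(x))) {
    x[l, ] <- signal::filtfilt(hp, x[l, ])
    x[l, ] <- signal::filtfilt(ns, x[l, ])
  }

  n_valid <- ncol(x)
  if (n_valid < target_len) {
    x <- cbind(x, matrix(0, nrow(x), target_len - n_valid))
  }
  rownames(x) <- record$lead_labels
  out <- ecg_record(x, fs = target_fs, ecg_id = record$ecg_id,
                    patient_id = record$patient_id,
                    acquisition_time = record$acquisition_time)
  attr(out, "n_valid") <- n_valid
  out
}

# small-denominator rational approximation of a resampling ratio
rational_ratio <- function(num, den, max_den = 1000) {
  r <- num / den
  best <- c(round(r), 1)
  best_err <- abs(r - best[1])
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    err <- abs(r - p / q)
    if (err < best_err - 1e-12) {
      best <- c(p, q); best_err <- err
      if (err < 1e-9) break
    }
  }
  as.integer(best)
}

#' Preprocess every trace of a cohort
#'
#' Applies [preprocess_trace()] to all ECGs and returns a cohort whose trace
#' array is `leads x target_len x n_ecgs` at `target_fs`, with a per-ECG
#' `n_valid` column recording how many samples precede the zero padding.
#'
#' @inheritParams preprocess_trace
#' @param cohort an [ecg_cohort()]
#' @return a preprocessed [ecg_cohort()]
#' @export
preprocess_cohort <- function(cohort, target_fs = 128, target_len = 512,
                              highpass_cutoff = 0.5, notch_freq = 50,
                              notch_q = 30) {
  m <- nrow(cohort$ecgs)
  out <- array(0, dim = c(dim(cohort$traces)[1], target_len, m),
               dimnames = list(dimnames(cohort$traces)[[1]], NULL, NULL))
  n_valid <- integer(m)
  for (i in seq_len(m)) {
    rec <- ecg_record(cohort$traces[, , i, drop = TRUE], fs = cohort$ecgs$fs[i])
    pp <- preprocess_trace(rec, target_fs, target_len,
                           highpass_cutoff, notch_freq, notch_q)
    out[, , i] <- pp$trace
    n_valid[i] <- attr(pp, "n_valid")
  }
  res <- cohort
  res$traces <- as_float32(out)
  dimnames(res$traces) <- dimnames(out)
  res$ecgs$fs <- target_fs
  res$ecgs$n_valid <- n_valid
  res$config$preprocess <- list(target_fs = target_fs, target_len = target_len,
                                highpass_cutoff = highpass_cutoff,
                                notch_freq = notch_freq, notch_q = notch_q)
  res
}
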