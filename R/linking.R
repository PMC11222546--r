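#' Link ECGs to lab targets within a time window
#'
#' An ECG is retained iff at least one lab measurement of the same patient
#' lies within `+/- window_minutes` (closed interval) of its acquisition
#' time. Its regression target is the median of all of that patient's lab
#' values inside the window; for an even count the median is the mean of the
#' two central values (the behaviour of [stats::median()]). ECGs with no lab
#' in window are dropped; the number dropped is reported as an attribute.
#'
#' @param ecgs data.frame with ecg_id, patient_id, acquisition_time
#' @param labs data.frame with patient_id, value, time (one analyte)
#' @param window_minutes half-width of the closed linking window
#' @return data.frame of linked examples (ecg_id, patient_id, target,
#'   n_labs_in_window), with attribute `n_dropped`
#' @export
link_ecg_lab <- function(ecgs, labs, window_minutes = 60) {
  if (length(unique(labs$analyte %||% "x")) > 1) {
    stop("labs must contain a single analyte", call. = FALSE)
  }
  w <- window_minutes * 60
  targets <- numeric(nrow(ecgs))
  counts <- integer(nrow(ecgs))
  lab_split <- split(seq_len(nrow(labs)), labs$patient_id)
  for (i in seq_len(nrow(ecgs))) {
    idx <- lab_split[[ecgs$patient_id[i]]]
    if (is.null(idx)) { counts[i] <- 0L; next }
    dt <- abs(as.numeric(difftime(labs$time[idx], ecgs$acquisition_time[i],
                                  units = "secs")))
    sel <- idx[dt <= w]
    counts[i] <- length(sel)
    if (length(sel) > 0) targets[i] <- stats::median(labs$value[sel])
  }
  keep <- counts >= 1L
  out <- data.frame(
    ecg_id = ecgs$ecg_id[keep],
    patient_id = ecgs$patient_id[keep],
    target = targets[keep],
    n_labs_in_window = counts[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Patient-level random/temporal dataset split
#'
#' Patients admitted on or after `cutoff_date` form the temporal test set.
#' The remaining patients are randomly partitioned between development
#' (train + validation) and the random test set in proportion
#' `fractions["dev"] : fractions["random"]`. Within development, a fraction
#' of patients (`val_fraction_of_dev`) is held out for validation. To keep
#' the temporal test set fully separated, ECGs of development / random-test
#' patients acquired on or after the cutoff are removed.
#'
#' @param patients data.frame with patient_id, admission_date
#' @param ecgs data.frame with ecg_id, patient_id, acquisition_time
#' @param cutoff_date temporal cutoff (default "2017-01-01")
#' @param fractions named fractions `c(dev=, temporal=, random=)`; the
#'   temporal entry is the nominal share, realized as the actually available
#'   post-cutoff patients
#' @param val_fraction_of_dev fraction of development patients used for
#'   validation
#' @param seed seed for the random partition
#' @return an object of class `dataset_splits`: per-partition patient id
#'   vectors, per-partition ECG id vectors (after post-cutoff removal), the
#'   ids of removed ECGs, cutoff, fractions and seed
#' @export
split_patients <- function(patients, ecgs, cutoff_date = "2017-01-01",
                           fractions = c(dev = 0.70, temporal = 0.10, random = 0.20),
                           val_fraction_of_dev = 0.10, seed = 1) {
  cutoff <- as.Date(cutoff_date)
  post <- patients$patient_id[patients$admission_date >= cutoff]
  if (length(post) == 0) {
    stop("temporal split empty: no patients admitted on/after the cutoff",
         call. = FALSE)
  }
  pre <- setdiff(patients$patient_id, post)

  with_local_seed(seed, {
    pre <- sample(pre)
    n_dev <- round(length(pre) * fractions[["dev"]] /
                     (fractions[["dev"]] + fractions[["random"]]))
    dev <- pre[seq_len(n_dev)]
    random_test <- pre[setdiff(seq_along(pre), seq_len(n_dev))]
    n_val <- round(length(dev) * val_fraction_of_dev)
    val <- if (n_val > 0) dev[seq_len(n_val)] else character(0)
    train <- setdiff(dev, val)

    cutoff_ts <- as.POSIXct(cutoff, tz = "UTC")
    pre_pat <- c(train, val, random_test)
    removed <- ecgs$ecg_id[ecgs$patient_id %in% pre_pat &
                             ecgs$acquisition_time >= cutoff_ts]
    keep <- !(ecgs$ecg_id %in% removed)

    ecg_ids <- function(pat) ecgs$ecg_id[keep & ecgs$patient_id %in% pat]
    structure(
      list(
        patients = list(train = train, val = val,
                        random_test = random_test, temporal_test = post),
        ecg_ids = list(train = ecg_ids(train), val = ecg_ids(val),
                       random_test = ecg_ids(random_test),
                       temporal_test = ecgs$ecg_id[ecgs$patient_id %in% post]),
        removed_ecg_ids = removed,
        cutoff_date = cutoff, fractions = fractions,
        val_fraction_of_dev = val_fraction_of_dev, seed = seed
      ),
      class = "dataset_splits"
    )
  })
}

#' Keep only the first ECG per patient in evaluation partitions
#'
#' Training keeps every linked ECG (multiple ECGs per patient act as data
#' augmentation); in validation and test partitions only the earliest ECG of
#' each patient is evaluated.
#'
#' @param linked linked examples from [link_ecg_lab()]
#' @param ecgs data.frame with ecg_id, acquisition_time
#' @param splits a [split_patients()] result
#' @return named list of linked-example data.frames: train, val,
#'   random_test, temporal_test
#' @export
select_eval_ecgs <- function(linked, ecgs, splits) {
  tm <- ecgs$acquisition_time[match(linked$ecg_id, ecgs$ecg_id)]
  pick_first <- function(ids) {
    sub <- linked[linked$ecg_id %in% ids, , drop = FALSE]
    t_sub <- tm[linked$ecg_id %in% ids]
    ord <- order(t_sub, sub$ecg_id)
    sub <- sub[ord, , drop = FALSE]
    sub[!duplicated(sub$patient_id), , drop = FALSE]
  }
  list(
    train = linked[linked$ecg_id %in% splits$ecg_ids$train, , drop = FALSE],
    val = pick_first(splits$ecg_ids$val),
    random_test = pick_first(splits$ecg_ids$random_test),
    temporal_test = pick_first(splits$ecg_ids$temporal_test)
  )
}

#' Fit a z-score normalizer on training targets
#'
#' Population-sd convention (divide by n). Parameters must come from the
#' training targets only; applying then inverting is the identity to machine
#' precision.
#'
#' @param y numeric training targets
#' @return object of class `norm_params` with fields mean, sd
#' @export
fit_normalizer <- function(y) {
  if (length(y) < 1 || any(!is.finite(y))) {
    stop("targets must be finite and non-empty", call. = FALSE)
  }
  m <- mean(y)
  s <- sqrt(mean((y - m)^2))
  if (s == 0) stop("degenerate targets: sd is zero", call. = FALSE)
  structure(list(mean = m, sd = s), class = "norm_params")
}

#' @rdname fit_normalizer
#' @param params a `norm_params`
#' @param x values on the original scale
#' @export
apply_normalizer <- function(x, params) (x - params$mean) / params$sd

#' @rdname fit_normalizer
#' @param z values on the normalized scale
#' @export
invert_normalizer <- function(z, params) z * params$sd + params$mean
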