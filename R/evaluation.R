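#' Sparsification curve
#'
#' For each removal fraction `f`, the MAE of the `(1 - f)` fraction of
#' examples with smallest uncertainty. Informative uncertainties give a
#' monotone non-increasing curve; ties are broken by stable input order.
#'
#' @param abs_errors per-example absolute errors
#' @param uncertainties per-example uncertainty values
#' @param fractions removal-fraction grid (must include 0 for the full-set
#'   MAE anchor)
#' @return data.frame: fraction_removed, n_kept, mae
#' @export
sparsification <- function(abs_errors, uncertainties,
                           fractions = seq(0, 0.9, by = 0.1)) {
  stopifnot(length(abs_errors) == length(uncertainties))
  n <- length(abs_errors)
  ord <- order(uncertainties) # radix sort: stable in input order on ties
  data.frame(
    fraction_removed = fractions,
    n_kept = vapply(fractions, function(f) as.integer(max(1, round((1 - f) * n))),
                    integer(1)),
    mae = vapply(fractions, function(f) {
      keep <- ord[seq_len(max(1L, round((1 - f) * n)))]
      mean(abs_errors[keep])
    }, numeric(1))
  )
}

#' Central-interval calibration curve
#'
#' For each nominal level q, the empirical fraction of targets inside the
#' central Gaussian q-interval around the predicted mean,
#' `mean +/- z_{(1+q)/2} * sd`. A calibrated model tracks the diagonal.
#'
#' @param mean predicted means
#' @param total_variance predicted total variances
#' @param targets observed values
#' @param levels nominal coverage levels
#' @return data.frame: nominal, empirical
#' @export
calibration_curve <- function(mean, total_variance, targets,
                              levels = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(all(total_variance >= 0))
  sd <- sqrt(total_variance)
  data.frame(
    nominal = levels,
    empirical = vapply(levels, function(q) {
      z <- stats::qnorm((1 + q) / 2)
      base::mean(abs(targets - mean) <= z * sd)
    }, numeric(1))
  )
}

#' Correlation between uncertainty estimates and squared error
#'
#' Pearson correlation of each estimate — and of the aleatoric estimate
#' summed with each epistemic one — with the per-example squared error.
#' Constant estimates yield NA with a warning.
#'
#' @param uncertainties named list of per-example variance vectors; names
#'   starting with "aleatoric" are treated as the aleatoric component for
#'   the summed combinations
#' @param squared_errors per-example squared errors
#' @return data.frame: estimate, correlation
#' @export
uncertainty_error_correlation <- function(uncertainties, squared_errors) {
  safe_cor <- function(u) {
    if (stats::sd(u) == 0 || stats::sd(squared_errors) == 0) {
      warning("constant input: correlation undefined", call. = FALSE)
      return(NA_real_)
    }
    stats::cor(u, squared_errors)
  }
  nm <- names(uncertainties)
  out <- data.frame(estimate = nm,
                    correlation = vapply(uncertainties, safe_cor, numeric(1)),
                    stringsAsFactors = FALSE)
  ale <- nm[startsWith(nm, "aleatoric")]
  if (length(ale) == 1) {
    for (ep in setdiff(nm, ale)) {
      out <- rbind(out, data.frame(
        estimate = paste(ale, "+", ep),
        correlation = safe_cor(uncertainties[[ale]] + uncertainties[[ep]])
      ))
    }
  }
  rownames(out) <- NULL
  out
}

valid_length <- function(x, i, n_valid = NULL) {
  if (!is.null(n_valid)) return(n_valid[i])
  nz <- which(colSums(abs(x[, , i, drop = TRUE])) > 0)
  if (length(nz) == 0) 0L else max(nz)
}

#' Add white Gaussian noise at a fixed signal-to-noise ratio
#'
#' Per trace, the signal power is the mean square over all leads of the
#' non-padded samples; noise with variance `power / snr` is added to that
#' region (the zero-padding tail is left untouched). `snr` is a linear
#' power ratio, not decibels.
#'
#' @param x trace array `leads x samples x n`
#' @param snr linear signal-to-noise power ratio, `> 0`
#' @param seed integer seed
#' @param n_valid optional per-trace count of non-padded samples; inferred
#'   from trailing all-zero columns when NULL
#' @return perturbed array
#' @export
perturb_noise <- function(x, snr, seed = 1, n_valid = NULL) {
  stopifnot_scalar_pos(snr, "snr")
  with_local_seed(seed, {
    out <- x
    for (i in seq_len(dim(x)[3])) {
      nv <- valid_length(x, i, n_valid)
      if (nv == 0) next
      seg <- x[, seq_len(nv), i, drop = TRUE]
      p <- mean(seg^2)
      if (p == 0) next
      noise <- matrix(stats::rnorm(length(seg)), nrow(seg))
      # rescale so the realized power ratio is exact, not just in expectation
      noise <- noise * sqrt(p / snr / mean(noise^2))
      out[, seq_len(nv), i] <- seg + noise
    }
    out
  })
}

#' Mask a proportion of each trace
#'
#' Sets exactly `round(proportion * samples)` samples per lead to zero, the
#' same time positions on every lead: one random contiguous segment
#' (default) or scattered random samples.
#'
#' @param x trace array `leads x samples x n`
#' @param proportion fraction of samples to mask, in `[0, 1]`
#' @param seed integer seed
#' @param mode "contiguous" or "scattered"
#' @return masked array
#' @export
perturb_mask <- function(x, proportion, seed = 1,
                         mode = c("contiguous", "scattered")) {
  mode <- match.arg(mode)
  if (proportion < 0 || proportion > 1) {
    stop("proportion must lie in [0, 1]", call. = FALSE)
  }
  L <- dim(x)[2]
  m <- round(proportion * L)
  if (m == 0) return(x)
  with_local_seed(seed, {
    out <- x
    for (i in seq_len(dim(x)[3])) {
      pos <- if (mode == "contiguous") {
        s <- sample.int(L - m + 1L, 1)
        s:(s + m - 1L)
      } else {
        sample.int(L, m)
      }
      out[, pos, i] <- 0
    }
    out
  })
}

#' Out-of-distribution uncertainty report
#'
#' Evaluates the ensemble on clean and perturbed copies of a test set and
#' tabulates, per condition: MAE (mean and sd over ensemble members) and
#' the mean per-example uncertainty (reported as sd, concentration units)
#' for the aleatoric Gaussian, epistemic ensemble and, when posteriors are
#' supplied, epistemic Laplace estimates.
#'
#' @param ensemble an `ecgnet_ensemble`
#' @param x clean trace array
#' @param y targets (concentration scale)
#' @param conditions named list of perturbation specs: NULL for the clean
#'   baseline, or `list(kind = "gaussian_noise", snr = )` /
#'   `list(kind = "masking", proportion = , mode = )`
#' @param posteriors optional list of `laplace_posterior` per member
#' @param seed seed for the perturbations
#' @param n_valid optional per-trace non-padded sample counts
#' @return data.frame with one row per condition
#' @export
ood_report <- function(ensemble, x, y,
                       conditions = list(baseline = NULL,
                                         snr10 = list(kind = "gaussian_noise", snr = 10),
                                         snr1 = list(kind = "gaussian_noise", snr = 1)),
                       posteriors = NULL, seed = 1, n_valid = NULL) {
  rows <- lapply(seq_along(conditions), function(ci) {
    spec <- conditions[[ci]]
    xi <- if (is.null(spec)) {
      x
    } else if (spec$kind == "gaussian_noise") {
      perturb_noise(x, spec$snr, seed = child_seed(seed, ci), n_valid = n_valid)
    } else if (spec$kind == "masking") {
      perturb_mask(x, spec$proportion, seed = child_seed(seed, ci),
                   mode = spec$mode %||% "contiguous")
    } else stop("unknown perturbation kind", call. = FALSE)
    preds <- ensemble_member_preds(ensemble, xi)
    maes <- vapply(preds, function(p) mean(abs(p$mean - y)), numeric(1))
    row <- data.frame(
      condition = names(conditions)[ci],
      mae = mean(maes),
      mae_sd = stats::sd(maes),
      aleatoric_gaussian = mean(sqrt(aleatoric_gaussian(ensemble, xi))),
      epistemic_ensemble = mean(sqrt(epistemic_ensemble(ensemble, xi))),
      stringsAsFactors = FALSE
    )
    if (!is.null(posteriors)) {
      row$epistemic_laplace <-
        mean(sqrt(epistemic_laplace(ensemble, posteriors, xi)))
    }
    row
  })
  do.call(rbind, rows)
}
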