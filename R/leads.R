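#' Augment an 8-lead trace to the standard 12 leads
#'
#' The four remaining limb leads are linear combinations of I and II
#' (Einthoven/Goldberger identities): `III = II - I`, `aVR = -(I + II)/2`,
#' `aVL = I - II/2`, `aVF = II - I/2`. Output lead order is the standard
#' I, II, III, aVR, aVL, aVF, V1-V6.
#'
#' @param trace8 8 x samples matrix with rownames I, II, V1-V6 (any order),
#'   or an [ecg_record()]
#' @return object of the same kind with 12 leads
#' @export
make_twelve_lead <- function(trace8) {
  if (inherits(trace8, "ecg_record")) {
    out <- trace8
    out$trace <- make_twelve_lead(trace8$trace)
    out$lead_labels <- rownames(out$trace)
    return(out)
  }
  if (!is.matrix(trace8) || is.null(rownames(trace8)) ||
      !setequal(rownames(trace8), LEADS8)) {
    stop("expected an 8-lead trace with leads I, II, V1-V6", call. = FALSE)
  }
  x <- trace8[LEADS8, , drop = FALSE]
  I <- x["I", ]; II <- x["II", ]
  out <- rbind(
    I = I, II = II,
    III = II - I,
    aVR = -(I + II) / 2,
    aVL = I - II / 2,
    aVF = II - I / 2,
    x[c("V1", "V2", "V3", "V4", "V5", "V6"), , drop = FALSE]
  )
  out[LEADS12, , drop = FALSE]
}

#' Reduce a 12-lead trace to the 8 independent leads
#'
#' Keeps I, II, V1-V6 in that fixed order; the discarded leads are exact
#' linear combinations of the retained ones and carry no extra information.
#'
#' @param record 12-lead (or already 8-lead) matrix with lead rownames, or an
#'   [ecg_record()]
#' @return the 8-lead object
#' @export
reduce_leads <- function(record) {
  if (inherits(record, "ecg_record")) {
    out <- record
    out$trace <- reduce_leads(record$trace)
    out$lead_labels <- rownames(out$trace)
    return(out)
  }
  if (!is.matrix(record) || is.null(rownames(record))) {
    stop("expected a lead-labelled trace matrix", call. = FALSE)
  }
  if (!all(LEADS8 %in% rownames(record))) {
    stop("lead mismatch: need leads I, II, V1-V6", call. = FALSE)
  }
  record[LEADS8, , drop = FALSE]
}
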