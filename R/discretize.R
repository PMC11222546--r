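#' Build a k-class interval scheme from training targets
#'
#' For `k = 3` the two bounds are `mu +/- 2*sigma` of the training targets;
#' for `k > 3`, the `k - 1` bounds are evenly spaced on
#' `[mu - 2*sigma, mu + 2*sigma]` inclusive of the two extremes (interior
#' spacing `4*sigma / (k - 2)`). Interval closure is left-open/right-closed
#' except the first class: a value equal to a bound belongs to the lower
#' class. Interior representative values are interval midpoints; the two
#' edge classes are represented by the midpoint between the edge bound and
#' the training minimum/maximum.
#'
#' @param k number of classes, `>= 3` (binary tasks use
#'   [build_binary_tasks()])
#' @param train_targets numeric training targets
#' @return object of class `interval_scheme` with fields k, bounds,
#'   representative_values, mu, sigma, train_range
#' @export
build_scheme <- function(k, train_targets) {
  k <- as.integer(k)
  if (k < 3) stop("build_scheme requires k >= 3", call. = FALSE)
  mu <- mean(train_targets)
  sigma <- sqrt(mean((train_targets - mu)^2))
  if (sigma == 0) stop("degenerate targets: sigma is zero", call. = FALSE)
  lo <- mu - 2 * sigma; hi <- mu + 2 * sigma
  bounds <- if (k == 3) c(lo, hi) else seq(lo, hi, length.out = k - 1)
  rng <- range(train_targets)
  reps <- numeric(k)
  reps[1] <- (rng[1] + bounds[1]) / 2
  reps[k] <- (bounds[k - 1] + rng[2]) / 2
  if (k > 2) {
    for (i in 2:(k - 1)) reps[i] <- (bounds[i - 1] + bounds[i]) / 2
  }
  structure(
    list(k = k, bounds = bounds, representative_values = reps,
         mu = mu, sigma = sigma, train_range = rng,
         construction = if (k == 3) "mu_2sigma" else "evenly_spaced"),
    class = "interval_scheme"
  )
}

#' Hypo/hyper binary decision tasks for an analyte
#'
#' Two independent one-vs-rest tasks: hypo (`y < hypo_bound`) and hyper
#' (`y > hyper_bound`), both strict inequalities, using the clinical bounds
#' of the [analyte_spec()] (potassium 3.5/5.5, calcium 2.0/2.75, sodium
#' 130/150 mmol/l). Analytes without agreed clinical bounds (creatinine)
#' fall back to `mu +/- 2*sigma` of the training targets unless
#' `use_clinical = TRUE` forces the profile bounds.
#'
#' @param analyte an [analyte_spec()]
#' @param train_targets training targets (for the fallback bounds)
#' @param use_clinical force the analyte's stored bounds even for analytes
#'   flagged for the fallback
#' @return object of class `binary_task_pair` with hypo_bound, hyper_bound,
#'   and `labels(y)` helpers
#' @export
build_binary_tasks <- function(analyte, train_targets = NULL,
                               use_clinical = FALSE) {
  fallback <- identical(analyte$name, "creatinine") && !use_clinical
  if (fallback) {
    if (is.null(train_targets)) {
      stop("fallback bounds need train_targets", call. = FALSE)
    }
    mu <- mean(train_targets)
    sigma <- sqrt(mean((train_targets - mu)^2))
    hypo <- mu - 2 * sigma; hyper <- mu + 2 * sigma
  } else {
    hypo <- analyte$hypo_bound; hyper <- analyte$hyper_bound
  }
  if (!(hypo < hyper)) stop("need hypo_bound < hyper_bound", call. = FALSE)
  structure(list(hypo_bound = hypo, hyper_bound = hyper,
                 source = if (fallback) "mu_2sigma" else "clinical"),
            class = "binary_task_pair")
}

#' @rdname build_binary_tasks
#' @param tasks a `binary_task_pair`
#' @param y concentrations to label
#' @return list of two logical vectors, `hypo` and `hyper`
#' @export
binary_labels <- function(tasks, y) {
  list(hypo = y < tasks$hypo_bound, hyper = y > tasks$hyper_bound)
}

#' Assign continuous targets to scheme classes
#'
#' `class = 1 + number of bounds strictly below y`: boundary values belong
#' to the lower class (right-closed intervals).
#'
#' @param y concentrations
#' @param scheme an [build_scheme()] result
#' @return integer classes in 1..k
#' @export
assign_class <- function(y, scheme) {
  1L + findInterval(y, scheme$bounds, left.open = TRUE)
}

#' Cumulative-threshold encoding of an ordinal class
#'
#' `target_j = 1` iff `class > j`, for `j = 1..k-1`. Class 1 encodes to all
#' zeros, class k to all ones.
#'
#' @param class integer class(es) in 1..k
#' @param k number of classes
#' @return a `k-1` vector, or a `(k-1) x n` matrix for vector input
#' @export
ordinal_encode <- function(class, k) {
  out <- vapply(class, function(cl) as.numeric(seq_len(k - 1) < cl),
                numeric(k - 1))
  if (length(class) == 1L) as.numeric(out) else {
    if (!is.matrix(out)) out <- matrix(out, nrow = 1)
    out
  }
}

#' Decode threshold probabilities to an ordinal class
#'
#' `class = 1 + #\{j : p_j > 0.5\}` over the `k - 1` thresholds — the
#' rank-consistent counting rule: elementwise-increasing probabilities can
#' never decrease the class.
#'
#' @param threshold_probs numeric vector of `k-1` probabilities, or a
#'   `(k-1) x n` matrix
#' @return integer class(es)
#' @export
ordinal_decode <- function(threshold_probs) {
  if (is.matrix(threshold_probs)) {
    1L + colSums(threshold_probs > 0.5)
  } else {
    1L + sum(threshold_probs > 0.5)
  }
}

#' Map predicted classes back to concentrations
#'
#' Interior classes map to their interval midpoint; the half-open edge
#' classes to the midpoint between the edge bound and the training-set
#' minimum/maximum (see [build_scheme()]).
#'
#' @param class integer class(es) in 1..k
#' @param scheme an [build_scheme()] result
#' @return concentrations
#' @export
class_to_value <- function(class, scheme) {
  scheme$representative_values[class]
}
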