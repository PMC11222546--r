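#' Internal: evaluate code under a local, seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded generator calls do not
#' disturb the caller's RNG stream. All randomized functions in the package
#' route their draws through this helper, which is what makes every output a
#' pure function of (config, seed).
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Internal: derive a child seed from a base seed
#'
#' Deterministic splitting of one user-facing seed into independent stream
#' seeds; keeps results below 2^31 - 1 so they remain valid R integers.
#' @keywords internal
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + 11 * as.double(index)) %% 2147483647)
}

#' Round doubles to the nearest single-precision value
#'
#' Cohort traces are stored on disk as 32-bit floats. Snapping in-memory
#' traces onto the float32 grid once at generation time makes the on-disk
#' round trip bit-exact.
#'
#' @param x numeric vector/array
#' @return numeric with the same shape, each value exactly representable in
#'   IEEE single precision
#' @export
as_float32 <- function(x) {
  dims <- dim(x)
  con <- rawConnection(raw(0), "r+")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(x), con, size = 4L)
  seek(con, 0L)
  out <- readBin(con, "numeric", n = length(x), size = 4L)
  dim(out) <- dims
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
  invisible(x)
}
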