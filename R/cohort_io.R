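#' Write a cohort to a directory container
#'
#' Layout: `traces.bin` (32-bit IEEE floats, little-endian, column-major with
#' leads fastest, then samples, then ECGs), `ecgs.csv`, `labs.csv`,
#' `patients.csv` (timestamps ISO-8601 UTC), and `provenance.json` (generator
#' config, seed, schema version, array dimensions). Because in-memory traces
#' are float32-snapped at generation ([as_float32()]), the round trip through
#' this container is bit-exact.
#'
#' @param cohort an [ecg_cohort()]
#' @param path directory to create/overwrite
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "ecg_cohort")) stop("need an ecg_cohort", call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  con <- file(file.path(path, "traces.bin"), "wb")
  writeBin(as.numeric(cohort$traces), con, size = 4L, endian = "little")
  close(con)

  # doubles go out at 17 significant digits so the text round trip is exact
  fmt_doubles <- function(df) {
    for (nm in names(df)) {
      if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
    df
  }
  ecgs <- cohort$ecgs
  ecgs$acquisition_time <- format(ecgs$acquisition_time, "%Y-%m-%dT%H:%M:%S",
                                  tz = "UTC")
  utils::write.csv(fmt_doubles(ecgs), file.path(path, "ecgs.csv"),
                   row.names = FALSE)

  labs <- cohort$labs
  labs$time <- format(labs$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(fmt_doubles(labs), file.path(path, "labs.csv"),
                   row.names = FALSE)

  patients <- cohort$patients
  patients$admission_date <- format(patients$admission_date, "%Y-%m-%d")
  utils::write.csv(fmt_doubles(patients), file.path(path, "patients.csv"),
                   row.names = FALSE)

  prov <- list(
    schema_version = cohort$schema_version,
    dims = dim(cohort$traces),
    lead_labels = dimnames(cohort$traces)[[1]],
    config = cohort$config
  )
  jsonlite::write_json(prov, file.path(path, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort container written by [write_cohort()]
#'
#' @param path container directory
#' @return an [ecg_cohort()]
#' @export
read_cohort <- function(path) {
  prov <- jsonlite::read_json(file.path(path, "provenance.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(prov$schema_version), COHORT_SCHEMA_VERSION)) {
    stop(sprintf("cohort schema version mismatch: file has %s, reader expects %s",
                 prov$schema_version, COHORT_SCHEMA_VERSION), call. = FALSE)
  }
  dims <- as.integer(prov$dims)

  con <- file(file.path(path, "traces.bin"), "rb")
  vals <- readBin(con, "numeric", n = prod(dims), size = 4L, endian = "little")
  close(con)
  traces <- array(vals, dim = dims,
                  dimnames = list(prov$lead_labels, NULL, NULL))

  # known double/integer columns are coerced explicitly; CSV type guessing
  # would demote e.g. a whole-number sampling rate to integer
  col_types <- list(
    ecgs = c(fs = "double", heart_rate = "double", gain = "double",
             trace_row = "integer", n_valid = "integer"),
    labs = c(value = "double"),
    patients = c(age = "double", latent_concentration = "double")
  )
  read_chr_csv <- function(f, types) {
    df <- utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)
    for (nm in intersect(names(types), names(df))) {
      df[[nm]] <- if (types[[nm]] == "integer") as.integer(df[[nm]])
                  else as.double(df[[nm]])
    }
    df
  }
  ecgs <- read_chr_csv("ecgs.csv", col_types$ecgs)
  if (nrow(ecgs) > 0) {
    ecgs$acquisition_time <- as.POSIXct(ecgs$acquisition_time,
                                        format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  } else {
    ecgs$acquisition_time <- as.POSIXct(character(0), tz = "UTC")
  }
  labs <- read_chr_csv("labs.csv", col_types$labs)
  if (nrow(labs) > 0) {
    labs$time <- as.POSIXct(labs$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  } else {
    labs$time <- as.POSIXct(character(0), tz = "UTC")
  }
  patients <- read_chr_csv("patients.csv", col_types$patients)
  patients$admission_date <- if (nrow(patients) > 0) {
    as.Date(patients$admission_date)
  } else {
    as.Date(character(0))
  }

  ecg_cohort(patients, ecgs, labs, traces,
             config = prov$config %||% list())
}
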