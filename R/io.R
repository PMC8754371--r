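#' Write / read a continuous recording (binary float + JSON sidecar)
#'
#' Interchange format for continuous recordings: a little-endian float32
#' array (channels x samples, channel-major) alongside a JSON sidecar
#' carrying the sampling rate and the per-contact metadata (channel names,
#' shaft, index, anatomical label, MNI coordinates, flags). Requires the
#' jsonlite package.
#'
#' @param rec A `contact_recording`.
#' @param path Path of the binary data file; the sidecar is `path` +
#'   `".json"`.
#' @return `read_recording` returns the `contact_recording`.
#' @export
write_recording <- function(rec, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for recording I/O")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$signal)), con, size = 4L, endian = "little")
  side <- list(rate = rec$rate, n_channels = nrow(rec$signal),
               n_samples = ncol(rec$signal), contact_meta = rec$contact_meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for recording I/O")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = side$n_channels * side$n_samples,
                 size = 4L, endian = "little")
  sig <- matrix(raw, nrow = side$n_channels, byrow = TRUE)
  structure(list(signal = sig, rate = side$rate,
                 contact_meta = as.data.frame(side$contact_meta)),
            class = "contact_recording")
}

#' Write / read an electrode contact table (TSV)
#'
#' Columns: `channel` (contact id), `shaft`, `index`, `label`, `x`, `y`,
#'   `z`, `in_brain`, `excluded`.
#'
#' @param meta Contact metadata data frame.
#' @param path File path.
#' @return `read_electrode_table` returns the data frame.
#' @export
write_electrode_table <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_electrode_table
#' @export
read_electrode_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Patient cohort characteristics
#'
#' The clinical characteristics table of the 11-patient cohort that
#' motivates the pipeline's default study conditions, including
#' State-Trait Anxiety Inventory (STAI) scores (one patient did not complete
#' the questionnaire; `NA`).
#'
#' @return Data frame with columns `patient`, `sex`, `age`, `handedness`,
#'   `seizure_onset_age`, `n_aed`, `epileptogenic_zone`, `stai`.
#' @export
#' @examples
#' cohort <- patient_cohort()
#' mean(cohort$stai, na.rm = TRUE)
patient_cohort <- function() {
  path <- system.file("extdata", "patient_cohort.tsv", package = "faceflow")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
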