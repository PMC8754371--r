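#' Construct an epoch set
#'
#' The common container for baseline z-scored (or raw) epoched data:
#' a trials x time x sites array with per-trial metadata, a time axis in
#' milliseconds relative to the locked event, and per-site metadata.
#'
#' @param data Numeric array, trials x time x sites (a trials x time matrix is
#'   promoted to a single-site array).
#' @param time_ms Numeric vector of sample times (ms) relative to `lock_event`.
#' @param lock_event `"Face1"` or `"Face2"`.
#' @param trials Data frame of per-trial metadata (one row per trial).
#' @param sites Data frame of per-site metadata (one row per site).
#' @param rate Sampling rate in Hz.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, lock_event = c("Face1", "Face2"),
                      trials = NULL, sites = NULL, rate = 400) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == length(time_ms))
  lock_event <- match.arg(lock_event)
  if (is.null(trials))
    trials <- data.frame(trial = seq_len(dim(data)[1]))
  if (is.null(sites))
    sites <- data.frame(site = paste0("s", seq_len(dim(data)[3])))
  stopifnot(nrow(trials) == dim(data)[1], nrow(sites) == dim(data)[3])
  structure(list(data = data, time_ms = time_ms, lock_event = lock_event,
                 trials = trials, sites = sites, rate = rate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "Epoch set: %d trials x %d samples x %d sites, locked to %s, %g Hz\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$lock_event, x$rate))
  cat(sprintf("  time %g .. %g ms\n", min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

# trials x time matrix for one site
site_matrix <- function(epochs, site = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data[, , site, drop = TRUE]
}

# column indices of a time window (ms); half-open or closed selectable
time_index <- function(time_ms, from, to, closed = TRUE) {
  if (closed) which(time_ms >= from & time_ms <= to)
  else which(time_ms >= from & time_ms < to)
}

#' Subset an epoch set by trials
#'
#' @param epochs An `epoch_set`.
#' @param keep Logical or integer index over trials.
#' @return The subsetted `epoch_set`.
#' @export
subset_trials <- function(epochs, keep) {
  stopifnot(inherits(epochs, "epoch_set"))
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trials <- epochs$trials[keep, , drop = FALSE]
  rownames(epochs$trials) <- NULL
  epochs
}
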