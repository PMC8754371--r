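#' Cut one long epoch per trial from a continuous recording
#'
#' Each trial is epoched from 400 ms before fixation onset to 1 s after
#' target onset (half-open sample interval `[start, end)`). On catch trials,
#' which carry no target, the end is anchored to the latest possible target
#' time (Face 2 onset + 450 ms maximum SOA) + 1 s, keeping windows
#' comparable.
#'
#' @param rec A `contact_recording`.
#' @param design A [build_trial_design()] table with absolute onset times.
#' @return An object of class `long_epochs`: per-trial channels x samples
#'   matrices, per-trial event sample indices (`fixation`, `face1`, `face2`,
#'   `target`), the channel metadata, the design, and a rejection `flags`
#'   table. Trials whose window falls outside the recording are flagged (not
#'   silently dropped).
#' @export
epoch_long_trials <- function(rec, design) {
  stopifnot(inherits(rec, "contact_recording"))
  fs <- rec$rate
  n_samp <- ncol(rec$signal)
  max_soa_s <- 0.45

  epochs <- vector("list", nrow(design))
  events <- vector("list", nrow(design))
  flags <- data.frame(trial = design$trial, block = design$block,
                      retained = rep(TRUE, nrow(design)),
                      reason = rep(NA_character_, nrow(design)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(design))) {
    start_s <- design$fixation_onset_s[i] - 0.4
    end_s <- if (isTRUE(design$catch[i]))
      design$face2_onset_s[i] + max_soa_s + 1 else design$target_onset_s[i] + 1
    # half-open sample window: times t with start <= t < end; the small
    # epsilon guards against decimal times that are not exact binary floats
    i0 <- floor(start_s * fs + 1e-6) + 1L
    i1 <- floor(end_s * fs + 1e-6)
    if (i0 < 1L || i1 > n_samp || !is.finite(i1)) {
      flags$retained[i] <- FALSE
      flags$reason[i] <- "outside_recording"
      next
    }
    epochs[[i]] <- rec$signal[, i0:i1, drop = FALSE]
    samp_of <- function(t_s) if (is.na(t_s)) NA_integer_ else
      as.integer(round(t_s * fs) + 1L - i0 + 1L)
    events[[i]] <- list(fixation = samp_of(design$fixation_onset_s[i]),
                        face1 = samp_of(design$face1_onset_s[i]),
                        face2 = samp_of(design$face2_onset_s[i]),
                        target = samp_of(design$target_onset_s[i]))
  }
  structure(list(epochs = epochs, events = events, design = design,
                 channels = rec$contact_meta, rate = fs, flags = flags),
            class = "long_epochs")
}

#' @export
print.long_epochs <- function(x, ...) {
  cat(sprintf("Long epochs: %d trials (%d retained), %d channels at %g Hz\n",
              length(x$epochs), sum(x$flags$retained),
              nrow(x$channels), x$rate))
  invisible(x)
}

#' Reject trials containing artifacts
#'
#' Applies, in order of precedence, (1) the +/-750 uV amplitude threshold on
#' any retained depth contact anywhere in the long epoch, (2) rejection of
#' trials with a marked epileptic/muscle/electrical artifact, and (3)
#' rejection of trials with a detected blink, where artifact and blink events
#' only count when they fall between 500 ms before Face 1 onset and 300 ms
#' after target onset (latest possible target time on catch trials). The
#' first criterion triggered is the one logged.
#'
#' @param long A `long_epochs` object with signal in microvolts
#'   (pre z-scoring).
#' @param artifact_events Optional data frame with a `time_s` column
#'   (absolute seconds) of marked epileptic/artifact events.
#' @param blink_events Optional data frame with a `time_s` column of blink
#'   events, e.g. from [detect_blinks()]; `NULL` skips the blink criterion.
#' @param threshold_uv Amplitude threshold (microvolts).
#' @return The `long_epochs` with updated `flags`; the rejection log is the
#'   `flags` table.
#' @export
reject_artifacts <- function(long, artifact_events = NULL, blink_events = NULL,
                             threshold_uv = 750) {
  stopifnot(inherits(long, "long_epochs"))
  depth <- which(!long$channels$excluded & long$channels$in_brain &
                   !isTRUE_col(long$channels$is_scalp))
  max_soa_s <- 0.45
  for (i in seq_along(long$epochs)) {
    if (!long$flags$retained[i]) next
    ep <- long$epochs[[i]]
    if (max(abs(ep[depth, , drop = FALSE])) > threshold_uv) {
      long$flags$retained[i] <- FALSE
      long$flags$reason[i] <- "threshold"
      next
    }
    t_face1 <- long$design$face1_onset_s[i]
    t_target <- if (isTRUE(long$design$catch[i]))
      long$design$face2_onset_s[i] + max_soa_s else long$design$target_onset_s[i]
    win <- c(t_face1 - 0.5, t_target + 0.3)
    in_win <- function(ev) !is.null(ev) && nrow(ev) > 0 &&
      any(ev$time_s >= win[1] & ev$time_s <= win[2])
    if (in_win(artifact_events)) {
      long$flags$retained[i] <- FALSE
      long$flags$reason[i] <- "epileptic/artifact"
      next
    }
    if (in_win(blink_events)) {
      long$flags$retained[i] <- FALSE
      long$flags$reason[i] <- "blink"
    }
  }
  long
}

isTRUE_col <- function(x) if (is.null(x)) FALSE else x

#' Detect blink events on a designated scalp channel
#'
#' Threshold detector standing in for interactive review: the scalp channel
#' is z-scored against its own median/MAD and excursions beyond `z_thresh`
#' are merged into events separated by at least `min_gap_s`.
#'
#' @param rec A `contact_recording`.
#' @param channel Channel name of the scalp electrode carrying blinks.
#' @param z_thresh Robust z threshold (detector parameter, not a protocol
#'   constant).
#' @param min_gap_s Minimum gap between distinct events (s).
#' @return Data frame with a `time_s` column, one row per detected blink.
#'   If the channel is absent, returns `NULL` with a warning.
#' @export
detect_blinks <- function(rec, channel = "scalp_blink", z_thresh = 5,
                          min_gap_s = 0.25) {
  ci <- match(channel, rec$contact_meta$channel)
  if (is.na(ci)) {
    warning("blink channel '", channel, "' absent; blink criterion skipped")
    return(NULL)
  }
  x <- rec$signal[ci, ]
  z <- (x - stats::median(x)) / (stats::mad(x) + 1e-12)
  above <- which(abs(z) > z_thresh)
  if (!length(above)) return(data.frame(time_s = numeric()))
  gaps <- which(diff(above) > min_gap_s * rec$rate)
  starts <- above[c(1L, gaps + 1L)]
  data.frame(time_s = (starts - 1) / rec$rate)
}

#' Apply behavioral trial exclusions
#'
#' Excludes trials with aberrant behavior, in order: responses before target
#' onset, misses (target trials without a press), false alarms (catch trials
#' with a press), then reaction times beyond 3 standard deviations of the
#' patient's mean RT (mean/SD computed on the RTs remaining at that point).
#' Finally, any block retaining fewer than 50% of its trials is dropped
#' entirely.
#'
#' @param long A `long_epochs` object.
#' @param responses Response table from [simulate_behavior()] or equivalent:
#'   columns `trial`, `pressed`, `rt_ms` (negative for pre-target presses).
#' @return The `long_epochs` with updated `flags`; block retention fractions
#'   are stored in `attr(flags, "block_retained")`.
#' @export
apply_behavioral_exclusions <- function(long, responses) {
  stopifnot(inherits(long, "long_epochs"))
  d <- long$design
  resp <- responses[match(d$trial, responses$trial), ]
  drop <- function(i, why) {
    sel <- i & long$flags$retained
    long$flags$retained[sel] <<- FALSE
    long$flags$reason[sel] <<- why
  }
  pre <- resp$pressed & !is.na(resp$rt_ms) & resp$rt_ms < 0
  drop(pre, "behavior_false_alarm")
  drop(!d$catch & !resp$pressed, "behavior_miss")
  drop(d$catch & resp$pressed, "behavior_false_alarm")
  ok_rt <- long$flags$retained & !d$catch & resp$pressed & !is.na(resp$rt_ms)
  if (sum(ok_rt) >= 2) {
    m <- mean(resp$rt_ms[ok_rt]); s <- stats::sd(resp$rt_ms[ok_rt])
    drop(ok_rt & abs(resp$rt_ms - m) > 3 * s, "behavior_rt_outlier")
  }
  blocks <- unique(d$block)
  frac <- vapply(blocks, function(b)
    mean(long$flags$retained[d$block == b]), 0)
  for (b in blocks[frac < 0.5])
    drop(d$block == b, "block_dropped")
  attr(long$flags, "block_retained") <- stats::setNames(frac, blocks)
  long
}

#' Extract short epochs locked to a face event and z-score to baseline
#'
#' Subdivides the long epochs into the analysis window of 100 ms prestimulus
#' to 400 ms poststimulus around Face 1 or Face 2 onset, and z-scores every
#' trial and channel against its own baseline (the 100 ms preceding the
#' locked onset, half-open `[-100, 0)` ms, so the onset sample itself is
#' excluded). Requires data at 400 Hz.
#'
#' @param long A `long_epochs` object at 400 Hz (see [downsample_to_400()]).
#' @param lock_event `"Face1"` or `"Face2"`.
#' @param zscore If `FALSE`, epochs are extracted without baseline scaling.
#' @return An `epoch_set` over retained trials. Trials whose baseline SD is
#'   zero on any channel are flagged degenerate and dropped (recorded in
#'   `attr(, "dropped")`).
#' @export
extract_and_zscore <- function(long, lock_event = c("Face1", "Face2"),
                               zscore = TRUE) {
  stopifnot(inherits(long, "long_epochs"))
  lock_event <- match.arg(lock_event)
  if (long$rate != 400)
    stop("epochs must be at 400 Hz; run downsample_to_400() first")
  time_ms <- seq(-100, 400, by = 2.5)
  pre <- 40L; post <- 160L                 # samples before/after onset
  base_idx <- seq_len(40L)                 # [-100, 0) ms
  keep <- which(long$flags$retained)
  n_ch <- nrow(long$channels)

  dat <- array(NA_real_, c(length(keep), length(time_ms), n_ch))
  degenerate <- logical(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    on <- long$events[[i]][[tolower(lock_event)]]
    idx <- (on - pre):(on + post)
    if (idx[1] < 1 || idx[length(idx)] > ncol(long$epochs[[i]])) {
      degenerate[k] <- TRUE
      next
    }
    ep <- t(long$epochs[[i]][, idx, drop = FALSE])  # time x channels
    if (zscore) {
      bm <- colMeans(ep[base_idx, , drop = FALSE])
      bs <- apply(ep[base_idx, , drop = FALSE], 2, stats::sd)
      if (any(bs == 0)) {
        degenerate[k] <- TRUE
        next
      }
      ep <- sweep(sweep(ep, 2, bm), 2, bs, "/")
    }
    dat[k, , ] <- ep
  }
  kept <- !degenerate
  meta_cols <- intersect(c("trial", "block", "emotion", "gaze", "catch"),
                         names(long$design))
  es <- epoch_set(dat[kept, , , drop = FALSE], time_ms, lock_event,
                  trials = long$design[keep[kept], meta_cols, drop = FALSE],
                  sites = long$channels, rate = 400)
  attr(es, "dropped") <- long$design$trial[keep[degenerate]]
  es
}

#' Summarize task behavior
#'
#' Computes the hit rate (proportion of target trials with a timely press),
#' the false-alarm rate (proportion of catch trials with a press), and the
#' mean reaction time after discarding RTs beyond 3 SD of the mean. Trials
#' with presses before target onset are excluded before all metrics.
#'
#' @param responses Response table (`trial`, `pressed`, `rt_ms`).
#' @param design The matching trial design.
#' @return A list of class `behavioral_summary`: `hit_rate`,
#'   `false_alarm_rate`, `mean_rt`, `rt_trim_bounds`, `n_targets`, `n_catch`.
#' @export
summarize_behavior <- function(responses, design) {
  resp <- responses[match(design$trial, responses$trial), ]
  pre <- resp$pressed & !is.na(resp$rt_ms) & resp$rt_ms < 0
  resp <- resp[!pre, ]; d <- design[!pre, ]
  targets <- !d$catch
  if (!any(targets)) {
    warning("no target trials; behavioral metrics undefined")
    return(structure(list(hit_rate = NA_real_, false_alarm_rate = NA_real_,
                          mean_rt = NA_real_, rt_trim_bounds = c(NA, NA),
                          n_targets = 0L, n_catch = sum(d$catch)),
                     class = "behavioral_summary"))
  }
  hit_rate <- mean(resp$pressed[targets])
  fa_rate <- if (any(d$catch)) mean(resp$pressed[d$catch]) else NA_real_
  rts <- resp$rt_ms[targets & resp$pressed & !is.na(resp$rt_ms)]
  bounds <- c(NA_real_, NA_real_); mean_rt <- NA_real_
  if (length(rts) >= 2) {
    bounds <- mean(rts) + c(-3, 3) * stats::sd(rts)
    mean_rt <- mean(rts[rts >= bounds[1] & rts <= bounds[2]])
  } else if (length(rts) == 1) mean_rt <- rts
  structure(list(hit_rate = hit_rate, false_alarm_rate = fa_rate,
                 mean_rt = mean_rt, rt_trim_bounds = bounds,
                 n_targets = sum(targets), n_catch = sum(d$catch)),
            class = "behavioral_summary")
}

#' @export
print.behavioral_summary <- function(x, ...) {
  cat(sprintf("Behavior: hit rate %.3f, false alarms %.3f, mean RT %.0f ms\n",
              x$hit_rate, x$false_alarm_rate, x$mean_rt))
  invisible(x)
}
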