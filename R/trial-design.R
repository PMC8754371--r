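#' Build a randomized trial design for the gaze/emotion face paradigm
#'
#' Generates the per-trial condition table for a Posner-like task in which a
#' neutral direct-gaze face (Face 1) turns happy or fearful while the gaze
#' averts left, averts right, or stays direct (Face 2), followed on most
#' trials by a lateral checkerboard target.
#'
#' Each block holds 108 trials: 54 happy and 54 fearful, crossed with 36
#' leftward, 36 rightward, and 36 direct-gaze trials (18 per emotion for each
#' gaze direction), of which 12 are catch trials (2 per emotion-by-gaze cell)
#' on which the target is omitted. Fixation duration is uniform on
#' [500, 800] ms, Face 1 duration uniform on [400, 600] ms (fixed at 500 ms
#' when `timing_jitter = FALSE`), and the target stimulus-onset asynchrony
#' after Face 2 is drawn from {300, 350, 400, 450} ms. Trial order is
#' randomized within block.
#'
#' @param n_blocks Number of blocks (>= 1). A full session is 8 blocks
#'   (864 trials, 96 catch trials).
#' @param timing_jitter If `FALSE`, the Face 1 duration is fixed at 500 ms
#'   (one patient in the motivating protocol had this fixed delay).
#' @param rng_seed Integer seed; identical seeds give identical tables.
#' @param iti_ms Inter-trial interval (ms) used when laying out absolute event
#'   times along a continuous recording.
#'
#' @return A `data.frame` of class `trial_design` with one row per trial and
#'   columns `trial`, `block`, `emotion` ("happy"/"fearful"), `gaze`
#'   ("left"/"right"/"direct"), `catch` (logical), `fixation_ms`, `face1_ms`,
#'   `soa_ms` (NA on catch trials), `target_side` ("left"/"right", NA on catch
#'   trials), and absolute onset times in seconds (`fixation_onset_s`,
#'   `face1_onset_s`, `face2_onset_s`, `target_onset_s`).
#' @export
#' @examples
#' d <- build_trial_design(1, rng_seed = 1)
#' nrow(d)      # 108
#' sum(d$catch) # 12
build_trial_design <- function(n_blocks, timing_jitter = TRUE, rng_seed = 1L,
                               iti_ms = 1000) {
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 1)
    stop("n_blocks must be a single integer >= 1")
  n_blocks <- as.integer(n_blocks)

  rng <- local_rng(rng_seed)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    # 6 emotion x gaze cells of 18 trials each; 2 catch per cell
    cells <- expand.grid(emotion = c("happy", "fearful"),
                         gaze = c("left", "right", "direct"),
                         stringsAsFactors = FALSE)
    tab <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(emotion = cells$emotion[i], gaze = cells$gaze[i],
                 catch = rep(c(TRUE, FALSE), c(2L, 16L)),
                 stringsAsFactors = FALSE)
    }))
    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    tab$block <- b
    tab$fixation_ms <- stats::runif(nrow(tab), 500, 800)
    tab$face1_ms <- if (timing_jitter) stats::runif(nrow(tab), 400, 600) else 500
    tab$soa_ms <- ifelse(tab$catch, NA_real_,
                         sample(c(300, 350, 400, 450), nrow(tab), replace = TRUE))
    tab$target_side <- ifelse(tab$catch, NA_character_,
                              sample(c("left", "right"), nrow(tab), replace = TRUE))
    tab
  })
  design <- do.call(rbind, blocks)
  design$trial <- seq_len(nrow(design))
  rownames(design) <- NULL

  # lay trials out along a continuous recording
  trial_span <- design$fixation_ms + design$face1_ms +
    ifelse(design$catch, max(c(300, 350, 400, 450)), design$soa_ms) + 1000
  start <- 2000 + c(0, cumsum(trial_span[-length(trial_span)] + iti_ms))
  design$fixation_onset_s <- start / 1000
  design$face1_onset_s <- (start + design$fixation_ms) / 1000
  design$face2_onset_s <- design$face1_onset_s + design$face1_ms / 1000
  design$target_onset_s <- ifelse(design$catch, NA_real_,
                                  design$face2_onset_s + design$soa_ms / 1000)

  design <- design[, c("trial", "block", "emotion", "gaze", "catch",
                       "fixation_ms", "face1_ms", "soa_ms", "target_side",
                       "fixation_onset_s", "face1_onset_s", "face2_onset_s",
                       "target_onset_s")]
  class(design) <- c("trial_design", "data.frame")
  design
}

#' Simulate button-press behavior for a trial design
#'
#' Draws per-trial responses for the detection task: hits with a configurable
#' rate and log-normal-ish reaction times, misses, false alarms on catch
#' trials, and occasional pre-target presses.
#'
#' @param design A `trial_design` table.
#' @param hit_rate Probability of responding on a target trial.
#' @param fa_rate Probability of a button press on a catch trial.
#' @param pre_target_rate Probability a press lands before target onset.
#' @param rt_mean,rt_sd Mean and SD (ms) of the reaction-time distribution.
#' @param rng_seed Integer seed.
#' @return A `data.frame` with columns `trial`, `pressed` (logical), `rt_ms`
#'   (relative to target onset; negative for pre-target presses; NA when no
#'   press or on catch trials where press time is relative to Face 2 + max
#'   SOA).
#' @export
simulate_behavior <- function(design, hit_rate = 0.99, fa_rate = 0.03,
                              pre_target_rate = 0.002, rt_mean = 357,
                              rt_sd = 60, rng_seed = 1L) {
  stopifnot(inherits(design, "data.frame"))
  rng <- local_rng(rng_seed)
  n <- nrow(design)
  pressed <- logical(n)
  rt <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (isTRUE(design$catch[i])) {
      pressed[i] <- stats::runif(1) < fa_rate
      if (pressed[i]) rt[i] <- stats::rnorm(1, rt_mean, rt_sd)
    } else {
      if (stats::runif(1) < pre_target_rate) {
        pressed[i] <- TRUE
        rt[i] <- -stats::runif(1, 20, 200)
      } else if (stats::runif(1) < hit_rate) {
        pressed[i] <- TRUE
        rt[i] <- max(120, stats::rnorm(1, rt_mean, rt_sd))
      }
    }
  }
  data.frame(trial = design$trial, pressed = pressed, rt_ms = rt)
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %d trials in %d block(s), %d catch trials\n",
              nrow(x), length(unique(x$block)), sum(x$catch)))
  NextMethod()
}

#' Write / read a trial design as tab-separated values
#'
#' @param design A `trial_design` table.
#' @param path File path.
#' @return `read_trial_design` returns the `trial_design` table.
#' @export
write_trial_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_design
#' @export
read_trial_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("trial_design", "data.frame")
  d
}

# Seed the RNG when a seed is supplied; NULL leaves the current stream alone.
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}
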