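#' ERP component description
#'
#' A single deflection of the evoked waveform, modeled as a Gaussian envelope:
#' `amplitude * exp(-(t - peak_latency)^2 / (2 * width^2))`. The component
#' inventory follows intracerebral face-evoked morphology: an early small
#' positive P100, a sharp negative N200 peaking at 150-200 ms, a following
#' positive P250, and (in superior temporal cortex, for static face onsets)
#' a slow negative wave peaking near 300 ms.
#'
#' @param label One of `"P100"`, `"N200"`, `"P250"`, `"slow_wave"`.
#' @param peak_latency Peak time (ms after stimulus onset).
#' @param amplitude Signed amplitude in baseline-SD (z) units. By convention
#'   N200 and slow-wave amplitudes are negative before any polarity flip.
#' @param width Gaussian SD of the envelope (ms), > 0.
#' @return A list of class `erp_component`.
#' @export
erp_component <- function(label, peak_latency, amplitude, width) {
  label <- match.arg(label, c("P100", "N200", "P250", "slow_wave"))
  stopifnot(width > 0)
  if (label %in% c("N200", "slow_wave") && amplitude > 0)
    stop(label, " amplitude must be negative by convention")
  structure(list(label = label, peak_latency = peak_latency,
                 amplitude = amplitude, width = width),
            class = "erp_component")
}

default_components <- function() {
  list(
    IOC = list(
      Face1 = list(erp_component("N200", 150, -3.0, 18),
                   erp_component("P250", 250, 1.2, 30)),
      Face2 = list(erp_component("N200", 160, -3.5, 18),
                   erp_component("P250", 255, 0.8, 30))),
    FC = list(
      Face1 = list(erp_component("P100", 100, 0.8, 15),
                   erp_component("N200", 180, -3.0, 20),
                   erp_component("P250", 260, 1.2, 30)),
      Face2 = list(erp_component("P100", 100, 0.6, 15),
                   erp_component("N200", 190, -3.0, 20))),
    ITC = list(
      Face1 = list(erp_component("P100", 100, 0.6, 15),
                   erp_component("N200", 180, -2.5, 20),
                   erp_component("P250", 260, 1.0, 30)),
      Face2 = list(erp_component("N200", 190, -2.5, 20))),
    STC = list(
      Face1 = list(erp_component("slow_wave", 300, -1.5, 45)),
      Face2 = list(erp_component("N200", 190, -2.5, 20))))
}

#' Simulation configuration for synthetic depth-electrode recordings
#'
#' Bundles the geometry, signal, noise, and planted-effect parameters that
#' drive [simulate_patient_recording()].
#'
#' @param shaft_layouts List of shaft descriptions, each a list with fields
#'   `shaft` (id), `label` (anatomical label from the controlled vocabulary),
#'   `from`, `to` (MNI mm, deep and shallow ends of the implanted segment),
#'   `spacing` (intercontact spacing, 5 or 10 mm), and optionally
#'   `reversal_after` (contact index after which the planted generator flips
#'   waveform polarity; `NA` for no reversal).
#' @param contacts_per_shaft Number of contacts per shaft (4-12 clinically).
#' @param sampling_rate 400 or 1024 Hz.
#' @param noise_sd Background noise SD in microvolts.
#' @param pink_noise_exponent Spectral exponent alpha of the 1/f^alpha
#'   background (1 = canonical pink local field potential noise).
#' @param white_noise_sd SD of the additional white-noise floor (microvolts).
#' @param component_params Per-ROI, per-lock-event lists of
#'   [erp_component()]s; defaults encode the N200-family morphology above.
#' @param effect_params Per-ROI planted condition effects: list with
#'   `gaze_amp`, `emo_amp` (additive z-unit amplitude change for averted gaze
#'   / fearful emotion applied to the dominant negative component),
#'   `gaze_lat`, `emo_lat` (ms latency shifts).
#' @param artifact_rates Named per-trial probabilities: `threshold`
#'   (amplitude excursion beyond 750 uV), `spike` (brief epileptiform-like
#'   transient), `blink` (slow wave on the designated scalp channel).
#' @param trial_amp_sd SD of the multiplicative per-trial amplitude
#'   variability (0 = identical evoked response every trial).
#' @param falloff_mm Gaussian spatial falloff (mm) of the evoked amplitude
#'   with distance from the planted generator (located between the
#'   polarity-reversal contacts, or mid-shaft when no reversal is planted);
#'   gives adjacent contacts unequal gains so bipolar sites away from the
#'   reversal still carry local signal.
#' @param rng_seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(shaft_layouts = default_shafts(),
                       contacts_per_shaft = 8L,
                       sampling_rate = 400,
                       noise_sd = 20,
                       pink_noise_exponent = 1,
                       white_noise_sd = 4,
                       component_params = default_components(),
                       effect_params = default_effects(),
                       artifact_rates = c(threshold = 0, spike = 0, blink = 0),
                       trial_amp_sd = 0.2,
                       falloff_mm = 12,
                       rng_seed = 1L) {
  if (!sampling_rate %in% c(400, 1024))
    stop("sampling_rate must be 400 or 1024 Hz")
  if (any(artifact_rates < 0) || any(artifact_rates > 1))
    stop("artifact rates must be probabilities in [0, 1]")
  for (sh in shaft_layouts)
    if (!is.null(sh$spacing) && sh$spacing <= 0) stop("spacing must be > 0")
  structure(list(shaft_layouts = shaft_layouts,
                 contacts_per_shaft = as.integer(contacts_per_shaft),
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 pink_noise_exponent = pink_noise_exponent,
                 white_noise_sd = white_noise_sd,
                 component_params = component_params,
                 effect_params = effect_params,
                 artifact_rates = artifact_rates,
                 trial_amp_sd = trial_amp_sd,
                 falloff_mm = falloff_mm,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

default_shafts <- function() {
  list(
    list(shaft = "e1", label = "inferior occipital gyrus",
         from = c(20, -92, -8), to = c(55, -92, -8), spacing = 5,
         reversal_after = 4L),
    list(shaft = "e2", label = "fusiform gyrus",
         from = c(20, -55, -20), to = c(55, -55, -20), spacing = 5,
         reversal_after = 4L),
    list(shaft = "e3", label = "inferior temporal gyrus",
         from = c(25, -55, -12), to = c(60, -55, -12), spacing = 5,
         reversal_after = NA),
    list(shaft = "e4", label = "superior temporal sulcus",
         from = c(25, -50, 4), to = c(60, -50, 4), spacing = 5,
         reversal_after = 4L))
}

default_effects <- function() {
  base <- list(gaze_amp = 0, emo_amp = 0, gaze_lat = 0, emo_lat = 0)
  list(IOC = base, FC = base, ITC = base,
       STC = modifyList(base, list(gaze_amp = -1.0)), other = base)
}

#' Generate 1/f^alpha "pink" noise
#'
#' Spectral-shaping generator: white Gaussian noise is filtered in the
#' frequency domain so its power spectrum follows 1/f^alpha, then rescaled to
#' unit standard deviation.
#'
#' @param n Number of samples.
#' @param alpha Spectral exponent (1 = pink).
#' @return Numeric vector of length `n` with mean ~0 and SD 1.
#' @export
pink_noise <- function(n, alpha = 1) {
  if (n < 2) return(stats::rnorm(n))
  m <- stats::nextn(n, 2)
  w <- stats::rnorm(m)
  spec <- stats::fft(w)
  f <- c(1, seq_len(m - 1))          # avoid dividing DC by zero
  f <- pmin(f, m - f + 1)            # mirror for negative frequencies
  spec <- spec / f^(alpha / 2)
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  x / stats::sd(x)
}

# Gaussian-envelope waveform on a ms time axis
component_wave <- function(time_ms, peak, amp, width) {
  amp * exp(-((time_ms - peak)^2) / (2 * width^2))
}

# condition-adjusted component list for one ROI/lock event
adjust_components <- function(comps, effects, emotion, gaze) {
  averted <- gaze %in% c("left", "right")
  fearful <- emotion == "fearful"
  lapply(comps, function(cp) {
    if (cp$label %in% c("N200", "slow_wave")) {
      cp$amplitude <- cp$amplitude +
        (if (averted) effects$gaze_amp else 0) +
        (if (fearful) effects$emo_amp else 0)
      cp$peak_latency <- cp$peak_latency +
        (if (averted) effects$gaze_lat else 0) +
        (if (fearful) effects$emo_lat else 0)
    }
    cp
  })
}

#' Simulate a continuous multi-contact depth-electrode recording
#'
#' Forward model for one synthetic patient session: for every trial, every
#' locked face event (Face 1 onset and the Face 2 gaze/emotion change)
#' contributes a sum of condition-dependent Gaussian-envelope ERP components
#' that is carried by every contact of the shaft with a per-contact polarity
#' sign (adjacent contacts straddling the planted generator have opposite
#' signs, producing the polarity reversals characteristic of local sources).
#' 1/f^alpha and white noise are added per contact, and artifacts (threshold
#' excursions, spike transients, and blink-like slow waves on a designated
#' scalp channel) are injected at configured per-trial rates.
#'
#' Component amplitudes are expressed in units of the background noise SD
#' (z units); they are scaled by `noise_sd` microvolts (or 1 if `noise_sd` is
#' 0, making the noiseless signal equal to the z-unit waveform).
#'
#' @param config A [sim_config()].
#' @param design A [build_trial_design()] table.
#' @return A list with `recording` (class `contact_recording`: `signal`
#'   channels x samples in microvolts, `rate`, `contact_meta`) and `truth`
#'   (planted component parameters per site and condition, per-contact
#'   polarity signs, injected artifact trials).
#' @export
simulate_patient_recording <- function(config, design) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(design) == 0L) stop("design is empty")
  local_rng(config$rng_seed)

  fs <- config$sampling_rate
  t_end <- max(design$face2_onset_s, na.rm = TRUE) + 2
  n_samp <- ceiling(t_end * fs)
  t_ms_step <- 1000 / fs

  # contact table
  meta <- do.call(rbind, lapply(config$shaft_layouts, function(sh) {
    n <- config$contacts_per_shaft
    dir <- (sh$to - sh$from) / sqrt(sum((sh$to - sh$from)^2))
    pos <- t(vapply(seq_len(n) - 1L, function(k) sh$from + dir * sh$spacing * k,
                    numeric(3)))
    data.frame(channel = paste0(sh$shaft, "-", seq_len(n)), shaft = sh$shaft,
               index = seq_len(n), label = sh$label,
               x = pos[, 1], y = pos[, 2], z = pos[, 3],
               in_brain = TRUE, excluded = FALSE, is_scalp = FALSE,
               stringsAsFactors = FALSE)
  }))
  meta <- rbind(meta, data.frame(channel = "scalp_blink", shaft = "scalp",
                                 index = 1L, label = "scalp", x = 0, y = 90,
                                 z = 40, in_brain = FALSE, excluded = FALSE,
                                 is_scalp = TRUE, stringsAsFactors = FALSE))
  rownames(meta) <- NULL
  n_chan <- nrow(meta)
  amp_scale <- if (config$noise_sd > 0) config$noise_sd else 1

  # per-contact polarity signs and spatial gains around the planted generator
  signs <- numeric(n_chan)
  gains <- numeric(n_chan)
  fall <- if (is.null(config$falloff_mm)) 12 else config$falloff_mm
  for (sh in config$shaft_layouts) {
    idx <- which(meta$shaft == sh$shaft)
    rev_after <- if (is.null(sh$reversal_after)) NA else sh$reversal_after
    s <- rep(1, length(idx))
    if (!is.na(rev_after)) s[meta$index[idx] > rev_after] <- -1
    signs[idx] <- s
    gen_index <- if (is.na(rev_after)) (length(idx) + 1) / 2
    else rev_after + 0.5
    dist_mm <- abs(meta$index[idx] - gen_index) * sh$spacing
    gains[idx] <- exp(-dist_mm^2 / (2 * fall^2))
  }
  signs[meta$is_scalp] <- 0
  gains[meta$is_scalp] <- 0

  rois <- vapply(meta$label, function(l) assign_roi(l, warn = FALSE)$roi, "")

  sig <- matrix(0, n_chan, n_samp)
  truth_comp <- list()
  trial_gain <- 1 + stats::rnorm(nrow(design), 0, config$trial_amp_sd)

  for (ev in c("Face1", "Face2")) {
    onset_s <- if (ev == "Face1") design$face1_onset_s else design$face2_onset_s
    for (ci in seq_len(n_chan)) {
      roi <- rois[ci]
      comps <- config$component_params[[roi]][[ev]]
      if (is.null(comps) || signs[ci] == 0) next
      eff <- config$effect_params[[roi]]
      if (is.null(eff)) eff <- list(gaze_amp = 0, emo_amp = 0,
                                    gaze_lat = 0, emo_lat = 0)
      for (tr in seq_len(nrow(design))) {
        emotion <- if (ev == "Face1") "neutral" else design$emotion[tr]
        gaze <- if (ev == "Face1") "direct" else design$gaze[tr]
        acomps <- adjust_components(comps, eff, emotion, gaze)
        i0 <- round(onset_s[tr] * fs) + 1L
        rel_ms <- (seq(i0 - 40, min(i0 + round(0.5 * fs), n_samp)) - i0) * t_ms_step
        idx <- seq(i0 - 40, i0 + length(rel_ms) - 41L)
        wav <- 0
        for (cp in acomps)
          wav <- wav + component_wave(rel_ms, cp$peak_latency,
                                      cp$amplitude, cp$width)
        sig[ci, idx] <- sig[ci, idx] +
          signs[ci] * gains[ci] * trial_gain[tr] * amp_scale * wav
        if (tr == 1L)
          truth_comp[[paste(meta$channel[ci], ev, sep = ".")]] <-
            list(channel = meta$channel[ci], lock_event = ev, roi = roi,
                 components = acomps, sign = signs[ci])
      }
    }
  }

  # background noise
  if (config$noise_sd > 0)
    for (ci in seq_len(n_chan))
      sig[ci, ] <- sig[ci, ] +
        config$noise_sd * pink_noise(n_samp, config$pink_noise_exponent) +
        stats::rnorm(n_samp, 0, config$white_noise_sd)

  # artifacts
  art <- data.frame(trial = integer(), type = character(),
                    time_s = numeric(), channel = character(),
                    stringsAsFactors = FALSE)
  depth_idx <- which(!meta$is_scalp)
  for (tr in seq_len(nrow(design))) {
    t0 <- design$face1_onset_s[tr]
    if (stats::runif(1) < config$artifact_rates[["threshold"]]) {
      ch <- sample(depth_idx, 1)
      at <- t0 + stats::runif(1, -0.3, 0.4)
      i0 <- round(at * fs) + 1L
      idx <- i0:min(i0 + round(0.05 * fs), n_samp)
      sig[ch, idx] <- sig[ch, idx] + 900
      art <- rbind(art, data.frame(trial = tr, type = "threshold", time_s = at,
                                   channel = meta$channel[ch]))
    }
    if (stats::runif(1) < config$artifact_rates[["spike"]]) {
      ch <- sample(depth_idx, 1)
      at <- t0 + stats::runif(1, -0.3, 0.4)
      i0 <- round(at * fs) + 1L
      idx <- i0:min(i0 + round(0.03 * fs), n_samp)
      sig[ch, idx] <- sig[ch, idx] +
        300 * exp(-((seq_along(idx) - 5)^2) / 8)
      art <- rbind(art, data.frame(trial = tr, type = "spike", time_s = at,
                                   channel = meta$channel[ch]))
    }
    if (stats::runif(1) < config$artifact_rates[["blink"]]) {
      ch <- which(meta$is_scalp)[1]
      at <- t0 + stats::runif(1, -0.3, 0.4)
      i0 <- round(at * fs) + 1L
      idx <- i0:min(i0 + round(0.3 * fs), n_samp)
      sig[ch, idx] <- sig[ch, idx] +
        150 * sin(pi * seq_along(idx) / length(idx))^2
      art <- rbind(art, data.frame(trial = tr, type = "blink", time_s = at,
                                   channel = meta$channel[ch]))
    }
  }

  rec <- structure(list(signal = sig, rate = fs, contact_meta = meta),
                   class = "contact_recording")
  truth <- list(components = truth_comp, polarity = signs, gains = gains,
                artifact_trials = art, trial_gain = trial_gain,
                effect_params = config$effect_params)
  list(recording = rec, truth = truth)
}

#' @export
print.contact_recording <- function(x, ...) {
  cat(sprintf("Contact recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$rate,
              ncol(x$signal) / x$rate))
  invisible(x)
}

#' Simulate a group of trial-averaged site ERPs for one region
#'
#' Generates per-site trial-averaged waveforms for latency-level analyses:
#' a shared Gaussian deflection whose peak latency, amplitude and residual
#' noise vary across sites. Defaults emulate z-scored bipolar averages over
#' ~50-100 trials: peak amplitude 3 z with 17% site-to-site scatter, 5 ms
#' site-to-site peak-latency scatter, and 1 z of residual waveform noise.
#'
#' @param n_sites Number of sites.
#' @param peak_ms True peak latency of the deflection (ms).
#' @param amp Signed peak amplitude (z units; negative for N200-like peaks).
#' @param width Gaussian envelope SD (ms).
#' @param latency_jitter_sd Site-to-site SD of the true peak latency (ms).
#' @param amp_jitter Relative SD of the site amplitude.
#' @param noise_sd Residual waveform noise SD (z units). The noise is
#'   band-limited (Gaussian-smoothed over `noise_corr_ms`), matching
#'   trial-averaged waveforms that passed the 40 Hz low-pass of the
#'   preprocessing cascade; the smoothness matters for the stability of
#'   peak-latency statistics.
#' @param noise_corr_ms Correlation scale (Gaussian kernel SD, ms) of the
#'   residual noise.
#' @param time_ms Time axis.
#' @param rng_seed Integer seed.
#' @return Sites x time matrix of waveforms.
#' @export
simulate_site_erps <- function(n_sites, peak_ms, amp = -3, width = 20,
                               latency_jitter_sd = 2, amp_jitter = 0.17,
                               noise_sd = 0.6, noise_corr_ms = 8,
                               time_ms = seq(-100, 400, by = 2.5),
                               rng_seed = NULL) {
  local_rng(rng_seed)
  dt <- time_ms[2] - time_ms[1]
  smooth_noise <- function(n) {
    if (noise_corr_ms <= 0) return(stats::rnorm(n))
    k <- stats::dnorm(seq(-4 * noise_corr_ms, 4 * noise_corr_ms, by = dt),
                      0, noise_corr_ms)
    k <- k / sum(k)
    pad <- length(k)
    x <- stats::filter(stats::rnorm(n + 2 * pad), k, sides = 2)
    x <- as.numeric(x[(pad + 1):(pad + n)])
    x / stats::sd(x)
  }
  t(vapply(seq_len(n_sites), function(i) {
    p <- peak_ms + stats::rnorm(1, 0, latency_jitter_sd)
    a <- amp * (1 + stats::rnorm(1, 0, amp_jitter))
    a * exp(-((time_ms - p)^2) / (2 * width^2)) +
      noise_sd * smooth_noise(length(time_ms))
  }, numeric(length(time_ms))))
}

#' Simulate baseline z-scored epochs at a single bipolar site
#'
#' Direct trial-level forward model used to study the statistical stages in
#' isolation (bypassing the continuous-recording path): each trial's waveform
#' is the sum of condition-adjusted Gaussian ERP components, scaled by a
#' multiplicative per-trial gain, plus white noise.
#'
#' @param conditions Data frame with columns `emotion` and `gaze` (one row per
#'   trial), or an integer number of trials (all neutral/direct).
#' @param components List of [erp_component()]s (base, direct-gaze condition).
#' @param effects Planted deltas applied to negative components as in
#'   [sim_config()]: list(`gaze_amp`, `emo_amp`, `gaze_lat`, `emo_lat`).
#' @param trial_amp_sd SD of the multiplicative per-trial gain.
#' @param noise_sd White-noise SD per sample (z units).
#' @param time_ms Time axis (ms); default the standard -100..400 ms window at
#'   400 Hz.
#' @param rng_seed Integer seed.
#' @return An `epoch_set` (single site) whose `"truth"` attribute records the
#'   planted per-condition waveforms and the analytic effect sizes of the
#'   window-averaged amplitude measure: `onesample_d` (per condition, over the
#'   dominant peak +/- 50 ms) and `gaze_d` / `emo_d` (two-sample, same
#'   window).
#' @export
simulate_epochs <- function(conditions, components = default_components()$FC$Face2,
                            effects = list(gaze_amp = 0, emo_amp = 0,
                                           gaze_lat = 0, emo_lat = 0),
                            trial_amp_sd = 0, noise_sd = 0.5,
                            time_ms = seq(-100, 400, by = 2.5),
                            rng_seed = NULL) {
  if (is.numeric(conditions) && length(conditions) == 1L)
    conditions <- data.frame(emotion = rep("neutral", conditions),
                             gaze = rep("direct", conditions))
  local_rng(rng_seed)
  n <- nrow(conditions)
  nt <- length(time_ms)

  shape_for <- function(emotion, gaze) {
    acomps <- adjust_components(components, effects, emotion, gaze)
    w <- numeric(nt)
    for (cp in acomps)
      w <- w + component_wave(time_ms, cp$peak_latency, cp$amplitude, cp$width)
    w
  }
  cell_key <- paste(conditions$emotion, conditions$gaze)
  shapes <- lapply(unique(cell_key), function(k) {
    i <- match(k, cell_key)
    shape_for(conditions$emotion[i], conditions$gaze[i])
  })
  names(shapes) <- unique(cell_key)

  gain <- 1 + stats::rnorm(n, 0, trial_amp_sd)
  dat <- matrix(stats::rnorm(n * nt, 0, noise_sd), n, nt)
  for (i in seq_len(n))
    dat[i, ] <- dat[i, ] + gain[i] * shapes[[cell_key[i]]]

  # analytic effect sizes of the peak +/- 50 ms window-mean measure
  neg <- which.min(Reduce(`+`, shapes) / length(shapes))
  peak_ms <- time_ms[neg]
  win <- time_ms >= peak_ms - 50 & time_ms <= peak_ms + 50
  nw <- sum(win)
  sigma_e <- noise_sd / sqrt(nw)
  wins <- vapply(shapes, function(s) mean(s[win]), 0)
  d_one <- wins / sqrt(trial_amp_sd^2 * wins^2 + sigma_e^2)
  two_sample_d <- function(keys_a, keys_b) {
    wa <- mean(wins[names(wins) %in% keys_a])
    wb <- mean(wins[names(wins) %in% keys_b])
    sda <- sqrt(trial_amp_sd^2 * wa^2 + sigma_e^2)
    sdb <- sqrt(trial_amp_sd^2 * wb^2 + sigma_e^2)
    (wa - wb) / sqrt((sda^2 + sdb^2) / 2)
  }
  keys <- names(shapes)
  averted <- keys[grepl(" left| right", keys)]
  direct <- keys[grepl(" direct", keys)]
  fearful <- keys[grepl("^fearful", keys)]
  happy <- keys[grepl("^happy", keys)]
  truth <- list(peak_ms = peak_ms, window_means = wins, onesample_d = d_one,
                gaze_d = if (length(averted) && length(direct))
                  two_sample_d(averted, direct) else NA_real_,
                emo_d = if (length(fearful) && length(happy))
                  two_sample_d(fearful, happy) else NA_real_,
                shapes = shapes)

  es <- epoch_set(dat, time_ms, "Face2",
                  trials = cbind(conditions,
                                 data.frame(trial = seq_len(n), catch = FALSE)),
                  sites = data.frame(site = "sim1", roi = "FC",
                                     hemisphere = "R"))
  attr(es, "truth") <- truth
  es
}
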