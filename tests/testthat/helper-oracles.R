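# Independent oracles used across tests. These deliberately avoid the
# package's own cluster/statistic internals: plain loops, stats:: fits, and
# exhaustive enumeration at tiny n.

# max |cluster mass| of a t trace: simple scan, same-sign contiguity
oracle_max_mass <- function(tvec, thr) {
  tvec[!is.finite(tvec)] <- 0
  best <- 0; cur <- 0; cur_sign <- 0
  for (v in tvec) {
    s <- if (v > thr) 1 else if (v < -thr) -1 else 0
    if (s != 0 && s == cur_sign) cur <- cur + v
    else { best <- max(best, abs(cur)); cur <- if (s != 0) v else 0
    cur_sign <- s }
  }
  max(best, abs(cur))
}

# exhaustive sign-flip null of the one-sample cluster test at small n:
# returns the exact p of the observed max cluster mass
oracle_exact_signflip_p <- function(x, cluster_alpha = 0.05) {
  n <- nrow(x)
  stopifnot(n <= 14)
  thr <- qt(1 - cluster_alpha / 2, df = n - 1)
  tstat <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, sd) / sqrt(n)
    mu / se
  }
  obs <- oracle_max_mass(tstat(x), thr)
  null <- numeric(2^n)
  for (k in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(k, 2^(0:(n - 1))) > 0, -1, 1)
    null[k + 1] <- oracle_max_mass(tstat(x * signs), thr)
  }
  mean(null >= obs)
}

# pooled-SD two-sample Cohen's d written out longhand
oracle_pooled_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  ma <- sum(a) / na; mb <- sum(b) / nb
  va <- sum((a - ma)^2) / (na - 1)
  vb <- sum((b - mb)^2) / (nb - 1)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  (ma - mb) / sp
}

# make an epoch_set directly from a trials x time matrix (single site)
make_epochs <- function(mat, time_ms = seq(-100, 400, by = 2.5),
                        trials = NULL, roi = "FC", hemisphere = "R") {
  epoch_set(mat, time_ms, "Face2", trials = trials,
            sites = data.frame(site = "s1", roi = roi,
                               hemisphere = hemisphere))
}

# trials table with balanced 2x2 gaze/emotion cells
balanced_trials <- function(n_per_cell) {
  cells <- expand.grid(emotion = c("happy", "fearful"),
                       gaze = c("direct", "left"),
                       stringsAsFactors = FALSE)
  d <- cells[rep(seq_len(4), each = n_per_cell), ]
  d$trial <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

# hand-built contact recording on one shaft
make_rec <- function(signal, rate = 400, n_contacts = nrow(signal),
                     shaft = "e1", label = "fusiform gyrus",
                     excluded = rep(FALSE, n_contacts)) {
  meta <- data.frame(channel = paste0(shaft, "-", seq_len(n_contacts)),
                     shaft = shaft, index = seq_len(n_contacts),
                     label = label,
                     x = 40 + 6 * (seq_len(n_contacts) - 1), y = -50, z = -20,
                     in_brain = TRUE, excluded = excluded, is_scalp = FALSE,
                     stringsAsFactors = FALSE)
  structure(list(signal = signal, rate = rate, contact_meta = meta),
            class = "contact_recording")
}

# minimal hand-built design rows with absolute event times
make_design <- function(fixation_s, face1_s, face2_s, target_s,
                        catch = rep(FALSE, length(fixation_s))) {
  n <- length(fixation_s)
  data.frame(trial = seq_len(n), block = rep(1L, n),
             emotion = rep(c("happy", "fearful"), length.out = n),
             gaze = rep(c("direct", "left"), length.out = n),
             catch = catch,
             fixation_ms = rep(NA_real_, n), face1_ms = rep(NA_real_, n),
             soa_ms = ifelse(catch, NA_real_, (target_s - face2_s) * 1000),
             target_side = ifelse(catch, NA_character_, "left"),
             fixation_onset_s = fixation_s, face1_onset_s = face1_s,
             face2_onset_s = face2_s,
             target_onset_s = ifelse(catch, NA_real_, target_s),
             stringsAsFactors = FALSE)
}

# waveform bank: per-site Gaussian negative peaks with latency jitter
make_site_erps <- function(n_sites, peak_ms, amp = -3, width = 20,
                           jitter_sd = 8, noise_sd = 0.1,
                           time_ms = seq(-100, 400, by = 2.5)) {
  t(vapply(seq_len(n_sites), function(i) {
    p <- peak_ms + rnorm(1, 0, jitter_sd)
    amp * exp(-((time_ms - p)^2) / (2 * width^2)) +
      rnorm(length(time_ms), 0, noise_sd)
  }, numeric(length(time_ms))))
}
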