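#' Group sites into coronal slices along the posterior-anterior axis
#'
#' FC, ITC and STC sites are partitioned by MNI y coordinate into five 10 mm
#' slices A-E covering [-81, -31) (half-open bins) and a sixth slice F for
#' the remaining anterior sites (y >= -31). IOC spans a narrow y range and is
#' pooled as a single "all" slice. Sites with y < -81 are assigned to slice A
#' with a warning.
#'
#' @param sites A `bipolar_sites` data frame (needs `roi` and `y`).
#' @return The input with a `slice` column added.
#' @export
slice_by_y <- function(sites) {
  breaks <- seq(-81, -31, by = 10)
  slice_of <- function(y) {
    if (y < -81) return("A*")                 # flagged below
    if (y >= -31) return("F")
    LETTERS[findInterval(y, breaks)]
  }
  sl <- vapply(sites$y, slice_of, "")
  sl[sites$roi == "IOC"] <- "all"
  if (any(sl == "A*")) {
    warning(sum(sl == "A*"), " site(s) posterior to y = -81 assigned to slice A")
    sl[sl == "A*"] <- "A"
  }
  sites$slice <- sl
  sites
}

#' Trial-averaged ERPs per site
#'
#' @param epochs An `epoch_set`.
#' @param trials Optional logical/integer trial subset (e.g. one condition).
#' @return Sites x time matrix of trial-averaged waveforms.
#' @export
average_erps <- function(epochs, trials = NULL) {
  dat <- epochs$data
  if (!is.null(trials)) dat <- dat[trials, , , drop = FALSE]
  t(apply(dat, c(2, 3), mean))
}

#' Rectify ERP polarity across sites and average
#'
#' Adjacent bipolar sites that straddle a local generator carry the same
#' waveform with opposite sign; a plain average across such sites cancels.
#' The rectification procedure: (1) average the *absolute* waveforms across
#' sites and find the latency of maximal activity within the given broad
#' window; (2) at each site, average the signed amplitude within +/-25 ms of
#' that latency; (3) multiply the site's whole time course by -1 when this
#' mean is positive; (4) average the rectified waveforms. The convention
#' makes the dominant deflection negative-going.
#'
#' The broad peak-search windows in this protocol are 0-170 ms (IOC both
#' faces, FC Face 1), 210-400 ms (STC Face 1 slow wave), and 0-210 ms
#' (FC/STC Face 2, ITC both faces).
#'
#' @param erps Sites x time matrix of trial-averaged waveforms (one or more
#'   rows).
#' @param time_ms Matching time axis (ms).
#' @param window Length-2 broad peak-search window (ms).
#' @return List of class `rectified_erp`: `signs` (per site, +/-1),
#'   `rectified` (sites x time), `mean` (group-mean waveform), `sem`,
#'   `peak_latency_ms` (of the initial absolute average), `window`,
#'   `time_ms`, `n`.
#' @export
rectify_group <- function(erps, time_ms, window) {
  if (is.vector(erps)) erps <- matrix(erps, nrow = 1)
  stopifnot(ncol(erps) == length(time_ms))
  if (window[1] < min(time_ms) || window[2] > max(time_ms))
    stop("peak-search window outside the epoch")
  widx <- time_index(time_ms, window[1], window[2])
  abs_mean <- colMeans(abs(erps))
  peak_i <- widx[which.max(abs_mean[widx])]   # ties: earliest (which.max)
  peak_ms <- time_ms[peak_i]

  around <- time_index(time_ms, peak_ms - 25, peak_ms + 25)
  if (length(around) < 2)
    warning("+/-25 ms window clipped at the epoch edge")
  site_means <- unname(rowMeans(erps[, around, drop = FALSE]))
  signs <- ifelse(site_means > 0, -1, 1)
  rect <- erps * signs
  gm <- colMeans(rect)
  sem <- if (nrow(erps) > 1) apply(rect, 2, stats::sd) / sqrt(nrow(erps))
  else rep(NA_real_, ncol(erps))
  structure(list(signs = signs, rectified = rect, mean = gm, sem = sem,
                 peak_latency_ms = peak_ms, window = window,
                 time_ms = time_ms, n = nrow(erps)),
            class = "rectified_erp")
}

#' @export
print.rectified_erp <- function(x, ...) {
  cat(sprintf(
    "Rectified ERP: %d site(s), peak at %g ms (search %g-%g ms), %d flipped\n",
    x$n, x$peak_latency_ms, x$window[1], x$window[2], sum(x$signs < 0)))
  invisible(x)
}

#' One-sample amplitude effect size around a group peak
#'
#' Measures, trial by trial and without any rectification, the mean signed
#' amplitude within +/-50 ms of the group peak latency, and summarizes it as
#' Cohen's d = mu/sigma (mean over trials divided by the across-trial SD).
#' Because the sign of d depends on the arbitrary polarity of the bipolar
#' derivation, the absolute value |d| is the quantity of interest, read
#' against the conventional 0.2 / 0.5 / 0.8 small/medium/large bands.
#'
#' @param epochs An `epoch_set`.
#' @param site Site index or name.
#' @param group_peak_latency_ms Group peak latency (ms), e.g. from
#'   [rectify_group()].
#' @param trials Optional trial subset.
#' @return List of class `amplitude_effect`: `trial_means`, `d`, `abs_d`,
#'   `band`, `window_ms`, `n_trials`. Zero trial variance flags `d` as
#'   undefined (NA, with a warning).
#' @export
amplitude_effect <- function(epochs, site = 1L, group_peak_latency_ms,
                             trials = NULL) {
  m <- site_matrix(epochs, resolve_site(epochs, site))
  if (is.vector(m)) m <- matrix(m, nrow = 1)
  if (!is.null(trials)) m <- m[trials, , drop = FALSE]
  w <- c(group_peak_latency_ms - 50, group_peak_latency_ms + 50)
  if (w[1] < min(epochs$time_ms) || w[2] > max(epochs$time_ms))
    warning("+/-50 ms amplitude window clipped at the epoch edge")
  idx <- time_index(epochs$time_ms, w[1], w[2])
  tm <- rowMeans(m[, idx, drop = FALSE])
  s <- stats::sd(tm)
  if (is.na(s) || s == 0) {
    warning("zero across-trial variance; d undefined")
    d <- NA_real_
  } else d <- mean(tm) / s
  structure(list(trial_means = tm, d = d, abs_d = abs(d),
                 band = effect_band(abs(d)), window_ms = w,
                 n_trials = length(tm)),
            class = "amplitude_effect")
}

effect_band <- function(abs_d) {
  if (is.na(abs_d)) return(NA_character_)
  if (abs_d >= 0.8) "large" else if (abs_d >= 0.5) "medium"
  else if (abs_d >= 0.2) "small" else "negligible"
}

# --- jackknife latency machinery ---------------------------------------

#' Peak latency of a waveform
#'
#' Locates the maximal negative (or positive) deflection within a window.
#' The discrete argmax (ties broken to the earliest latency) is refined by
#' default with a three-point parabolic fit through the peak sample and its
#' neighbours, giving a sub-sample latency; this removes the sampling-grid
#' quantization that otherwise destabilizes jackknife variance estimates of
#' peak latencies. `refine = "none"` returns the raw grid latency.
#'
#' @param wave Numeric waveform.
#' @param time_ms Time axis (ms), uniformly sampled.
#' @param window Length-2 search window (ms).
#' @param peak_mode `"negative"` or `"positive"`.
#' @param refine `"parabolic"` (default) or `"none"`.
#' @return Peak latency in ms. Errors on a flat waveform.
#' @export
peak_latency <- function(wave, time_ms, window, peak_mode = "negative",
                         refine = c("parabolic", "none")) {
  refine <- match.arg(refine)
  idx <- time_index(time_ms, window[1], window[2])
  v <- wave[idx]
  if (max(v) == min(v)) stop("flat waveform: no peak")
  if (peak_mode == "negative") v <- -v
  i <- which.max(v)
  lat <- time_ms[idx[i]]
  if (refine == "parabolic" && i > 1 && i < length(v)) {
    den <- v[i - 1] - 2 * v[i] + v[i + 1]
    if (den < 0) {
      dt <- time_ms[2] - time_ms[1]
      lat <- lat + dt * 0.5 * (v[i - 1] - v[i + 1]) / den
    }
  }
  lat
}

# leave-one-out latencies of the mean waveform over sites
jackknife_latencies <- function(erps, time_ms, window,
                                peak_mode = "negative", latency_fn = NULL) {
  n <- nrow(erps)
  if (is.null(latency_fn))
    latency_fn <- function(sub) peak_latency(colMeans(sub), time_ms, window,
                                             peak_mode)
  vapply(seq_len(n), function(i)
    latency_fn(erps[-i, , drop = FALSE]), 0)
}

#' Jackknife standard deviation of a leave-one-out statistic
#'
#' The plain SD of leave-one-out values underestimates the sampling SD of
#' the full-sample statistic by roughly a factor (n - 1); the standard
#' jackknife inflation `sigma = sqrt((n-1)/n * sum((theta_i - theta_bar)^2))`
#' corrects this. For a linear statistic (a plain mean) the inflated value
#' equals the analytic standard error of the mean exactly.
#'
#' @param theta_loo Leave-one-out statistic values.
#' @param inflate Apply the inflation factor (default) or return the plain
#'   SD of the leave-one-out values.
#' @return The jackknife SD.
#' @export
jackknife_sd <- function(theta_loo, inflate = TRUE) {
  n <- length(theta_loo)
  if (inflate) sqrt((n - 1) / n * sum((theta_loo - mean(theta_loo))^2))
  else stats::sd(theta_loo)
}

#' Compare ERP peak latencies between two conditions by the jackknife
#'
#' Peak latencies of group-average waveforms are unstable at single sites;
#' the jackknife instead re-averages the rectified waveforms over all sites
#' minus one, measures the peak latency of each leave-one-out average, and
#' uses the (inflated) SD of those latencies as the uncertainty of the
#' full-sample latency. Conditions A and B are compared with
#' `t = (mu_A - mu_B) / sigma_AB`, `sigma_AB = sqrt(sigma_A^2 + sigma_B^2)`,
#' with `df = n_A + n_B - 2`; a two-sided p and the 95% confidence interval
#' of the latency difference are derived from the t distribution.
#'
#' @param erps_a,erps_b Sites x time matrices of rectified waveforms for the
#'   two conditions.
#' @param time_ms Shared time axis (ms).
#' @param window_a,window_b Peak-search windows (ms) per condition.
#' @param peak_mode_a,peak_mode_b `"negative"` (N200-type peak) or
#'   `"positive"`; the slow Face 1 deflection in STC uses the maximum of the
#'   (rectified) slow wave, i.e. still `"negative"` after rectification.
#' @param inflate Use the jackknife inflation factor (default).
#' @param latency_fn Optional override: function(sites x time matrix) ->
#'   latency, for non-default statistics.
#' @return List of class `jackknife_latency`: `mu_a`, `mu_b` (full-sample
#'   latencies, ms), `diff`, `sigma_a`, `sigma_b`, `sigma_ab`, `t`, `df`,
#'   `p`, `ci` (95%, ms), `latencies_a`, `latencies_b` (leave-one-out).
#' @export
jackknife_latency_compare <- function(erps_a, erps_b, time_ms,
                                      window_a = c(0, 400),
                                      window_b = window_a,
                                      peak_mode_a = "negative",
                                      peak_mode_b = peak_mode_a,
                                      inflate = TRUE, latency_fn = NULL) {
  if (nrow(erps_a) < 2 || nrow(erps_b) < 2)
    stop("need at least 2 sites per condition")
  lat_fn_a <- latency_fn
  lat_fn_b <- latency_fn
  full_a <- if (is.null(latency_fn))
    peak_latency(colMeans(erps_a), time_ms, window_a, peak_mode_a)
  else latency_fn(erps_a)
  full_b <- if (is.null(latency_fn))
    peak_latency(colMeans(erps_b), time_ms, window_b, peak_mode_b)
  else latency_fn(erps_b)
  loo_a <- jackknife_latencies(erps_a, time_ms, window_a, peak_mode_a, lat_fn_a)
  loo_b <- jackknife_latencies(erps_b, time_ms, window_b, peak_mode_b, lat_fn_b)
  s_a <- jackknife_sd(loo_a, inflate)
  s_b <- jackknife_sd(loo_b, inflate)
  s_ab <- sqrt(s_a^2 + s_b^2)
  dif <- full_a - full_b
  tval <- if (s_ab == 0) { if (dif == 0) 0 else sign(dif) * Inf } else dif / s_ab
  df <- nrow(erps_a) + nrow(erps_b) - 2
  p <- 2 * stats::pt(-abs(tval), df)
  ci <- dif + c(-1, 1) * stats::qt(0.975, df) * s_ab
  structure(list(mu_a = full_a, mu_b = full_b, diff = dif,
                 sigma_a = s_a, sigma_b = s_b, sigma_ab = s_ab,
                 t = tval, df = df, p = p, ci = ci,
                 latencies_a = loo_a, latencies_b = loo_b),
            class = "jackknife_latency")
}

#' @export
print.jackknife_latency <- function(x, ...) {
  cat(sprintf(
    "Jackknife latency: %.1f vs %.1f ms, t(%d) = %.2f, p = %.4g, CI [%.0f, %.0f]\n",
    x$mu_a, x$mu_b, x$df, x$t, x$p, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Pairwise and omnibus latency comparisons across ROIs
#'
#' Runs a jackknife latency comparison for every pair of ROIs (six tests for
#' four ROIs), Bonferroni-corrected at `0.05 / n_pairs_run`, and an omnibus
#' one-way ANOVA on the leave-one-out latencies with the jackknife F
#' correction (the raw F computed on leave-one-out values is divided by
#' `(n - 1)^2`, the mean per-group n, because jackknife values are
#' (n-1)-fold compressed around the mean).
#'
#' @param roi_erps Named list (one entry per ROI) of sites x time rectified
#'   waveform matrices.
#' @param time_ms Shared time axis.
#' @param windows Named list of per-ROI peak-search windows (default
#'   0-400 ms).
#' @param peak_modes Named character vector of per-ROI peak modes.
#' @param alpha Family-wise level.
#' @return List of class `roi_latency_comparison`: `pairwise` (data frame
#'   with `roi_a`, `roi_b`, latencies, `t`, `df`, `p`, `alpha_corrected`,
#'   `significant`), `omnibus` (list `F`, `F_corrected`, `df1`, `df2`, `p`),
#'   `latencies` (full-sample per ROI).
#' @export
compare_rois <- function(roi_erps, time_ms, windows = NULL,
                         peak_modes = NULL, alpha = 0.05) {
  rois <- names(roi_erps)
  stopifnot(length(rois) >= 2)
  win_of <- function(r) if (is.null(windows[[r]])) c(0, 400) else windows[[r]]
  mode_of <- function(r) if (is.null(peak_modes[[r]])) "negative"
  else peak_modes[[r]]

  prs <- utils::combn(rois, 2)
  rows <- list()
  for (k in seq_len(ncol(prs))) {
    a <- prs[1, k]; b <- prs[2, k]
    if (nrow(roi_erps[[a]]) < 2 || nrow(roi_erps[[b]]) < 2) {
      warning("pair ", a, "-", b, " skipped: fewer than 2 sites")
      next
    }
    jk <- jackknife_latency_compare(roi_erps[[a]], roi_erps[[b]], time_ms,
                                    win_of(a), win_of(b),
                                    mode_of(a), mode_of(b))
    rows[[length(rows) + 1L]] <-
      data.frame(roi_a = a, roi_b = b, mu_a = jk$mu_a, mu_b = jk$mu_b,
                 t = jk$t, df = jk$df, p = jk$p, stringsAsFactors = FALSE)
  }
  pairwise <- do.call(rbind, rows)
  pairwise$alpha_corrected <- alpha / nrow(pairwise)
  pairwise$significant <- pairwise$p < pairwise$alpha_corrected

  # omnibus jackknife ANOVA
  loo <- lapply(rois, function(r)
    jackknife_latencies(roi_erps[[r]], time_ms, win_of(r), mode_of(r)))
  vals <- unlist(loo)
  grp <- factor(rep(rois, vapply(loo, length, 0L)), levels = rois)
  fit <- stats::anova(stats::lm(vals ~ grp))
  F_raw <- fit$`F value`[1]
  nbar <- mean(vapply(loo, length, 0L))
  F_corr <- F_raw / (nbar - 1)^2
  omnibus <- list(F = F_raw, F_corrected = F_corr,
                  df1 = fit$Df[1], df2 = fit$Df[2],
                  p = stats::pf(F_corr, fit$Df[1], fit$Df[2],
                                lower.tail = FALSE))
  lat_full <- vapply(rois, function(r)
    peak_latency(colMeans(roi_erps[[r]]), time_ms, win_of(r), mode_of(r)), 0)
  structure(list(pairwise = pairwise, omnibus = omnibus,
                 latencies = lat_full),
            class = "roi_latency_comparison")
}

#' @export
print.roi_latency_comparison <- function(x, ...) {
  cat("ROI latency comparison\n")
  print(format(x$pairwise, digits = 3))
  cat(sprintf("Omnibus jackknife ANOVA: F(%d,%d) = %.2f (corrected), p = %.4g\n",
              x$omnibus$df1, x$omnibus$df2, x$omnibus$F_corrected,
              x$omnibus$p))
  invisible(x)
}
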