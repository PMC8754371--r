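#' Apply the standard filter cascade to a continuous recording
#'
#' The cascade used before epoching is a 0.3 Hz high-pass (order-4
#' Butterworth), two band-stop filters at 48-52 Hz and 58-66 Hz (order-4
#' Butterworth) against line noise, and a 40 Hz low-pass (order-6
#' Butterworth). All filters are applied zero-phase (forward-backward, via
#' [signal::filtfilt()]) so that ERP peak latencies are not shifted; signal
#' length is preserved.
#'
#' The low-pass stage is conventionally deferred until after artifact
#' rejection; `stages` selects which stages to run so the pipeline can split
#' the cascade.
#'
#' @param rec A `contact_recording` (or a plain channels x samples matrix
#'   with a `rate` argument).
#' @param stages Character subset of `c("highpass", "notch", "lowpass")`.
#' @param rate Sampling rate, required when `rec` is a bare matrix.
#' @return The filtered recording, same class and dimensions as the input.
#' @export
apply_filters <- function(rec, stages = c("highpass", "notch", "lowpass"),
                          rate = NULL) {
  stages <- match.arg(stages, c("highpass", "notch", "lowpass"),
                      several.ok = TRUE)
  bare <- !inherits(rec, "contact_recording")
  sig <- if (bare) rec else rec$signal
  fs <- if (bare) rate else rec$rate
  if (is.null(fs)) stop("sampling rate unknown")
  if (!all(is.finite(sig))) stop("signal contains non-finite values")
  if (fs <= 2 * 66 && "notch" %in% stages)
    stop("sampling rate too low for the 58-66 Hz band-stop")
  if (is.vector(sig)) sig <- matrix(sig, nrow = 1)

  filts <- filter_cascade(fs, stages)
  for (f in filts)
    for (ch in seq_len(nrow(sig)))
      sig[ch, ] <- signal::filtfilt(f, sig[ch, ])

  if (bare) sig else { rec$signal <- sig; rec }
}

# the designed Butterworth cascade for a given rate
filter_cascade <- function(fs, stages = c("highpass", "notch", "lowpass")) {
  ny <- fs / 2
  filts <- list()
  if ("highpass" %in% stages)
    filts <- c(filts, list(signal::butter(4, 0.3 / ny, type = "high")))
  if ("notch" %in% stages)
    filts <- c(filts, list(signal::butter(4, c(48, 52) / ny, type = "stop"),
                           signal::butter(4, c(58, 66) / ny, type = "stop")))
  if ("lowpass" %in% stages)
    filts <- c(filts, list(signal::butter(6, 40 / ny, type = "low")))
  filts
}

#' Single-pass magnitude response of the filter cascade at given frequencies
#'
#' Evaluates the product of the designed transfer functions at `freq_hz`.
#' The zero-phase (forward-backward) application squares this magnitude.
#'
#' @param fs Sampling rate (Hz).
#' @param freq_hz Frequencies (Hz) at which to evaluate.
#' @param stages Stages included in the cascade.
#' @return Numeric vector of single-pass magnitudes `|H(f)|`.
#' @export
cascade_response <- function(fs, freq_hz,
                             stages = c("highpass", "notch", "lowpass")) {
  filts <- filter_cascade(fs, stages)
  w <- 2 * pi * freq_hz / fs
  mag <- rep(1, length(w))
  for (f in filts) {
    h <- vapply(w, function(wi) {
      z <- exp(-1i * wi * seq(0, length(f$b) - 1))
      num <- sum(f$b * z)
      z <- exp(-1i * wi * seq(0, length(f$a) - 1))
      abs(num / sum(f$a * z))
    }, 0)
    mag <- mag * h
  }
  mag
}

#' Downsample epoched or continuous data to 400 Hz
#'
#' Data acquired at 1024 Hz are brought onto the common 400 Hz grid by linear
#' interpolation, which is accurate to better than 0.1% for any component
#' below the 40 Hz low-pass applied earlier in the pipeline. 400 Hz input is
#' returned bit-identical. Treating an `n`-sample input as the half-open span
#' `[0, n/1024)` s, the output holds every 400 Hz sample time inside that
#' span: `n_out = ceiling(n * 400/1024)` samples (the final sample, when it
#' falls past the last input time, extends the last input value).
#'
#' @param x A `contact_recording`, `long_epochs` object, numeric matrix
#'   (channels x samples) or vector.
#' @param rate Input sampling rate, required for bare matrices/vectors.
#' @return Same class as the input, at 400 Hz.
#' @export
downsample_to_400 <- function(x, rate = NULL) {
  if (inherits(x, "contact_recording")) {
    if (x$rate == 400) return(x)
    check_rate(x$rate)
    x$signal <- resample_mat(x$signal, x$rate)
    x$rate <- 400
    return(x)
  }
  if (inherits(x, "long_epochs")) {
    if (x$rate == 400) return(x)
    check_rate(x$rate)
    ratio <- 400 / x$rate
    x$epochs <- lapply(x$epochs, function(m) t(resample_mat(t(m), x$rate)))
    x$events <- lapply(x$events, function(ev) {
      ev_s <- lapply(ev, function(i) if (is.na(i)) NA_integer_ else
        as.integer(floor((i - 1) * ratio) + 1L))
      ev_s
    })
    x$rate <- 400
    return(x)
  }
  if (is.null(rate)) stop("rate required for bare input")
  if (rate == 400) return(x)
  check_rate(rate)
  if (is.vector(x)) drop(resample_mat(matrix(x, 1), rate)) else
    resample_mat(x, rate)
}

check_rate <- function(rate) {
  if (!rate %in% c(400, 1024))
    stop("unsupported sampling rate: ", rate, " (expected 400 or 1024 Hz)")
}

resample_mat <- function(sig, rate_in) {
  n_in <- ncol(sig)
  t_in <- (seq_len(n_in) - 1) / rate_in
  n_out <- as.integer(ceiling(n_in * 400 / rate_in - 1e-9))
  t_out <- (seq_len(n_out) - 1) / 400
  out <- matrix(0, nrow(sig), n_out)
  for (ch in seq_len(nrow(sig)))
    out[ch, ] <- stats::approx(t_in, sig[ch, ], xout = t_out, rule = 2)$y
  out
}
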