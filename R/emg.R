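# EMG envelope preprocessing chain:
# zero-phase low-pass (250 Hz) -> zero-phase 60 Hz notch -> full-wave
# rectification -> 250 ms sliding RMS -> normalization to the MVC peak.

# Forward-backward IIR filtering with odd-reflection edge padding, so edge
# transients decay inside the padding rather than in the returned series.
# Pad length must exceed the filter settling time (narrow notches ring for
# ~2Q/w0 seconds).
zero_phase_filter <- function(b, a, x, pad = 1000L) {
  n <- length(x)
  p <- min(pad, n - 1L)
  if (p > 0) {
    head_pad <- 2 * x[1] - x[(p + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  y <- signal::filtfilt(signal::Arma(b = b, a = a), xp)
  as.numeric(y[(p + 1L):(p + n)])
}

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' giving an effective 8th-order magnitude response and zero phase shift.
#'
#' @param x Numeric series.
#' @param cutoff Cutoff frequency, Hz; must be below Nyquist.
#' @param sample_rate Sampling rate, Hz.
#' @param order Filter order before the forward-backward pass.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, cutoff = 250, sample_rate = 1000, order = 4) {
  stopifnot_scalar(cutoff, "cutoff", positive = TRUE)
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (cutoff >= sample_rate / 2) {
    stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  zero_phase_filter(bf$b, bf$a, x, pad = 50L)
}

#' Zero-phase IIR notch filter
#'
#' Second-order IIR notch (biquad) at `center` Hz with quality factor `q`,
#' applied forward-backward for zero phase. Used to suppress mains
#' interference at 60 Hz.
#'
#' @param x Numeric series.
#' @param center Notch center frequency, Hz; in (0, Nyquist).
#' @param sample_rate Sampling rate, Hz.
#' @param q Quality factor (center / -3 dB bandwidth).
#' @return Filtered series, same length as `x`.
#' @export
notch_filter <- function(x, center = 60, sample_rate = 1000, q = 30) {
  stopifnot_scalar(center, "center", positive = TRUE)
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (center >= sample_rate / 2) {
    stop("`center` must be below the Nyquist frequency", call. = FALSE)
  }
  w0 <- 2 * pi * center / sample_rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  # settling time ~ 2 q / w0 seconds; pad generously beyond it
  pad <- as.integer(ceiling(6 * q / (2 * pi * center) * sample_rate))
  zero_phase_filter(b / a[1], a / a[1], x, pad = pad)
}

#' Full-wave rectification
#'
#' @param x Numeric series.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Sliding root-mean-square envelope
#'
#' RMS over a centered window of `window` seconds; windows are truncated at
#' the series edges so the output has the same length as the input.
#'
#' @param x Numeric series (typically rectified EMG).
#' @param window Window width, s.
#' @param sample_rate Sampling rate, Hz.
#' @return RMS-smoothed series, same length as `x`.
#' @export
rms_envelope <- function(x, window = 0.25, sample_rate = 1000) {
  w <- as.integer(round(window * sample_rate))
  if (w < 1) stop("`window` must span at least one sample", call. = FALSE)
  n <- length(x)
  if (w > n) stop("`window` is longer than the signal", call. = FALSE)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  cs <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Normalize an envelope to its MVC peak
#'
#' @param envelope Nonnegative series in signal units.
#' @param mvc_peak Peak processed envelope from the maximum voluntary
#'   contraction, same units; strictly positive.
#' @return Envelope in percent of MVC.
#' @export
normalize_to_mvc <- function(envelope, mvc_peak) {
  stopifnot_scalar(mvc_peak, "mvc_peak", positive = TRUE)
  envelope / mvc_peak * 100
}

#' Full EMG processing chain for one channel
#'
#' Applies, in order: zero-phase 250 Hz low-pass, zero-phase 60 Hz notch,
#' full-wave rectification, 250 ms sliding RMS, and MVC normalization.
#'
#' @param raw Raw EMG series.
#' @param mvc_peak MVC peak envelope in signal units (strictly positive), or
#'   `NULL` to skip normalization and return the envelope in signal units.
#' @param sample_rate Sampling rate, Hz.
#' @param lowpass_cutoff,notch_center,rms_window Chain constants.
#' @return Envelope series (percent MVC when `mvc_peak` is given).
#' @export
process_channel <- function(raw, mvc_peak = NULL, sample_rate = 1000,
                            lowpass_cutoff = 250, notch_center = 60,
                            rms_window = 0.25) {
  x <- lowpass_filter(raw, lowpass_cutoff, sample_rate)
  x <- notch_filter(x, notch_center, sample_rate)
  x <- rectify(x)
  x <- rms_envelope(x, rms_window, sample_rate)
  if (is.null(mvc_peak)) x else normalize_to_mvc(x, mvc_peak)
}

#' Process all EMG channels of a trial
#'
#' @param trial A `trial_recording` with an EMG matrix.
#' @param ref The matching [participant_reference()] (for MVC peaks).
#' @param ... Passed to [process_channel()].
#' @return `n x 8` matrix of envelopes in percent MVC, columns per
#'   [muscle_names()].
#' @export
process_trial_emg <- function(trial, ref, ...) {
  if (is.null(trial$emg)) stop("trial has no EMG data", call. = FALSE)
  out <- trial$emg
  for (c_i in 1:8) {
    out[, c_i] <- process_channel(trial$emg[, c_i],
                                  mvc_peak = ref$mvc_emg_peak[c_i],
                                  sample_rate = trial$sample_rate, ...)
  }
  out
}
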