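#' Remove the acquisition DC offset from a trace
#'
#' Subtracts the trace median, the package's estimator of the constant
#' offset introduced by the acquisition board. The median is used rather
#' than the mean because the breath waveform is asymmetric around its
#' baseline.
#'
#' @param trace a [resp_trace()].
#' @return The trace with `median(samples)` subtracted.
#' @export
remove_offset <- function(trace) {
  if (length(trace$samples) < 2L)
    stop_respstage("trace must contain at least 2 samples", "respstage_invalid_input")
  resp_trace(trace$samples - stats::median(trace$samples), dt = trace$dt,
             start_time = trace$start_time, stage = trace$stage)
}

#' Split a trace into consecutive analysis windows
#'
#' Non-overlapping consecutive windows of `window_length` seconds. A
#' trailing remainder shorter than half a window is dropped; otherwise it
#' is kept as a short final window.
#'
#' @param trace a [resp_trace()].
#' @param window_length window length in seconds (default 30, the sensor's
#'   epoch length).
#' @return List of [resp_trace()] windows with correct `start_time`s.
#' @export
segment_windows <- function(trace, window_length = 30) {
  if (window_length < 2 * trace$dt)
    stop_respstage("window_length must span at least 2 samples",
                   "respstage_invalid_parameter")
  nw <- round(window_length / trace$dt)
  n <- length(trace$samples)
  nfull <- n %/% nw
  rem <- n - nfull * nw
  bounds <- (0:nfull) * nw
  if (rem >= nw / 2) bounds <- c(bounds, n)
  out <- vector("list", length(bounds) - 1L)
  for (i in seq_along(out)) {
    idx <- (bounds[i] + 1L):bounds[i + 1L]
    out[[i]] <- resp_trace(trace$samples[idx], dt = trace$dt,
                           start_time = trace$start_time + bounds[i] * trace$dt,
                           stage = trace$stage)
  }
  out
}

#' Dominant respiration frequency of a window
#'
#' Frequency of the maximal FFT magnitude within the physiological
#' respiration band (default 0.1-0.5 Hz). The transform is zero-padded so
#' the frequency grid is at least as fine as `resolution`, allowing
#' frequencies to be reported well below the raw 1/window resolution.
#' No taper is applied by default.
#'
#' @param window a [resp_trace()], offset-removed.
#' @param band two-element numeric, the search band \[f_lo, f_hi\] in Hz.
#' @param resolution maximum frequency-grid spacing in Hz (default 0.002).
#' @param taper optional taper function applied to the samples before the
#'   transform, e.g. `function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)`;
#'   `NULL` (default) uses a rectangular window.
#' @return Dominant frequency in Hz.
#' @export
#' @examples
#' t <- seq(0, 120, by = 0.017)
#' w <- resp_trace(sin(2 * pi * 0.272 * t), dt = 0.017)
#' dominant_frequency(w)
dominant_frequency <- function(window, band = c(0.1, 0.5), resolution = 0.002,
                               taper = NULL) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop_respstage("band must satisfy 0 < f_lo < f_hi", "respstage_invalid_parameter")
  x <- window$samples
  if (length(x) < 4L)
    stop_respstage("window too short for spectral analysis", "respstage_invalid_input")
  if (max(abs(x)) == 0)
    stop_respstage("all-zero window: no spectral peak", "respstage_no_signal")
  if (!is.null(taper)) x <- x * taper(length(x))
  dt <- window$dt
  n_min <- ceiling(1 / (resolution * dt))
  n_pad <- 2^ceiling(log2(max(n_min, length(x))))
  mag <- Mod(stats::fft(c(x, numeric(n_pad - length(x)))))
  freqs <- (seq_len(n_pad) - 1) / (n_pad * dt)
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (max(mag[in_band]) <= 1e-12 * length(x))
    stop_respstage("no spectral peak above the numerical floor in band",
                   "respstage_no_signal")
  freqs[in_band[which.max(mag[in_band])]]
}

#' Convert a breath frequency to a respiration rate
#'
#' @param freq frequency in Hz (>= 0).
#' @return Respiration rate in breaths per minute, exactly `60 * freq`
#'   (0.272 Hz -> 16.32 b/min).
#' @export
respiration_rate <- function(freq) {
  check_finite(freq, "freq")
  if (any(freq < 0))
    stop_respstage("frequency must be non-negative", "respstage_invalid_input")
  60 * freq
}

#' Peak output voltage of a window
#'
#' Detects per-breath positive voltage peaks and summarizes their heights.
#' A sample is a peak candidate if it is a local maximum with topographic
#' prominence of at least `prominence_frac` times the window's maximum
#' absolute value; peaks closer than `0.5 / f_hi` seconds (half the period
#' of the fastest in-band breath) are merged, keeping the higher one.
#'
#' @param window a [resp_trace()], offset-removed.
#' @param f_hi upper edge of the respiration band in Hz; sets the minimum
#'   peak separation `0.5 / f_hi` seconds.
#' @param prominence_frac minimum peak prominence as a fraction of
#'   `max(abs(samples))`.
#' @param summary `"mean"` (default, robust to a single outlier breath) or
#'   `"max"`.
#' @return Summary of detected peak heights in volts.
#' @export
peak_output_voltage <- function(window, f_hi = 0.5, prominence_frac = 0.2,
                                summary = c("mean", "max")) {
  summary <- match.arg(summary)
  x <- window$samples
  if (length(x) < 3L || max(abs(x)) == 0)
    stop_respstage("no peaks detected in window", "respstage_no_signal")
  n <- length(x)
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > 0]
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
    cand <- cand[prom >= prominence_frac * max(abs(x))]
  }
  if (!length(cand))
    stop_respstage("no peaks detected in window", "respstage_no_signal")
  min_sep <- (0.5 / f_hi) / window$dt
  keep <- logical(length(cand))
  for (j in order(-x[cand], cand)) {
    if (!any(keep & abs(cand - cand[j]) < min_sep)) keep[j] <- TRUE
  }
  heights <- x[sort(cand[keep])]
  switch(summary, mean = mean(heights), max = max(heights))
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two lowest points separating it from higher terrain (or the
# window edge) on each side.
peak_prominence <- function(x, i) {
  left <- if (i > 1) x[1:(i - 1)] else numeric(0)
  right <- if (i < length(x)) x[(i + 1):length(x)] else numeric(0)
  base_side <- function(side, rev = FALSE) {
    if (!length(side)) return(-Inf)
    if (rev) side <- rev(side)
    higher <- which(side > x[i])
    if (length(higher)) min(side[1:higher[1]]) else min(side)
  }
  x[i] - max(base_side(left, rev = TRUE), base_side(right))
}

#' Extract (respiration rate, output voltage) features
#'
#' Runs the full per-window feature extraction: segment into
#' `window_length`-second windows, remove the DC offset per window, take
#' the FFT dominant frequency in `band` converted to breaths/minute, and
#' the mean per-breath peak voltage. Each window inherits the stage label
#' of the epoch containing its midpoint.
#'
#' @param x a `sleep_session` (see [synth_session()]) or a [resp_trace()].
#' @param window_length analysis window length in seconds (default 30).
#' @param band respiration frequency band in Hz.
#' @param hypnogram optional hypnogram data frame (`start_s`, `duration_s`,
#'   `stage`) used to label windows when `x` is a bare trace.
#' @param resolution frequency-grid spacing, see [dominant_frequency()].
#' @param prominence_frac,summary peak rules, see [peak_output_voltage()].
#' @return Data frame with columns `window_start_s`, `rate_bpm`, `voltage`
#'   (volts), `stage` (factor, `NA` when unlabeled).
#' @export
extract_features <- function(x, window_length = 30, band = c(0.1, 0.5),
                             hypnogram = NULL, resolution = 0.002,
                             prominence_frac = 0.2, summary = "mean") {
  if (inherits(x, "sleep_session")) {
    hypnogram <- x$hypnogram
    trace <- session_trace(x)
  } else if (inherits(x, "resp_trace")) {
    trace <- x
  } else {
    stop_respstage("x must be a sleep_session or resp_trace", "respstage_invalid_input")
  }
  windows <- segment_windows(trace, window_length)
  n <- length(windows)
  out <- data.frame(window_start_s = numeric(n), rate_bpm = numeric(n),
                    voltage = numeric(n),
                    stage = as_stage(rep(NA_character_, n)))
  for (i in seq_len(n)) {
    w <- remove_offset(windows[[i]])
    res <- tryCatch(
      list(rate = respiration_rate(
             dominant_frequency(w, band = band, resolution = resolution)),
           volt = peak_output_voltage(w, f_hi = band[2],
                                      prominence_frac = prominence_frac,
                                      summary = summary)),
      respstage_no_signal = function(e)
        stop_respstage(sprintf("window %d: %s", i, conditionMessage(e)),
                       "respstage_no_signal"))
    out$window_start_s[i] <- w$start_time
    out$rate_bpm[i] <- res$rate
    out$voltage[i] <- res$volt
    if (!is.null(hypnogram)) {
      mid <- w$start_time + window_length / 2
      j <- findInterval(mid, hypnogram$start_s)
      if (j >= 1 && j <= nrow(hypnogram)) out$stage[i] <- hypnogram$stage[j]
    }
  }
  out
}
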