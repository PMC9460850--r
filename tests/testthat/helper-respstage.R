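# Shared fixtures, built in code.

# A stage model with all dispersion switched off: exactly periodic breathing.
noiseless_model <- function(freq = 0.272, amp = 7.89, stage = "AWAKE") {
  list(stage = stage, breath_freq_mean = freq, breath_freq_sd = 0,
       amp_mean = amp, amp_sd = 0, breath_period_cv = 0, breath_amp_cv = 0)
}

# Pure sinusoid trace (zero-mean, so already offset-free).
sine_trace <- function(freq, duration = 120, dt = 0.017, amplitude = 1) {
  t <- (seq_len(round(duration / dt)) - 1) * dt
  resp_trace(amplitude * sin(2 * pi * freq * t), dt = dt)
}

# Independent oracle for dominant_frequency: dense direct Fourier magnitude
# evaluated on an explicit in-band grid (no FFT, no padding tricks).
direct_dft_peak <- function(x, dt, band = c(0.1, 0.5), df = 0.001) {
  freqs <- seq(band[1], band[2], by = df)
  t <- (seq_along(x) - 1) * dt
  mag <- vapply(freqs, function(f) Mod(sum(x * exp(-2i * pi * f * t))),
                numeric(1))
  freqs[which.max(mag)]
}

# Well-separated Gaussian clouds in the scaled plane, one per stage.
separated_clouds <- function(n_per = 30, sd = 0.02, sep = 1) {
  centers <- data.frame(x = sep * c(0, 1, 2, 3, 4), y = sep * c(0, 1, 0, 1, 0),
                        stage = stage_levels())
  pts <- do.call(rbind, lapply(seq_len(5), function(i) {
    data.frame(x = stats::rnorm(n_per, centers$x[i], sd),
               y = stats::rnorm(n_per, centers$y[i], sd),
               stage = centers$stage[i])
  }))
  list(points = pts, centers = centers)
}
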