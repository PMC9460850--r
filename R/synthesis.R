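#' Default per-stage generative signal models
#'
#' One generative model per sleep stage, parameterising the synthetic
#' mask-sensor respiration signal: the dominant breath frequency and its
#' across-epoch spread, the breath amplitude (open-circuit voltage at the
#' breath plateau) and its spread, and per-breath coefficient-of-variation
#' jitter for period and amplitude.
#'
#' Dominant frequencies default to the stage-specific values observed for
#' this sensor class: 0.272 (awake), 0.264 (N1), 0.233 (N2), 0.210 (N3) and
#' 0.292 Hz (REM). Amplitude means decrease through the non-REM depths
#' (parasympathetic activation weakens airflow), starting from the 7.89 V
#' normal nasal-breath output; REM keeps the awake-level mean but with
#' markedly larger variability, emulating the irregular REM breathing
#' pattern. The dispersion defaults are synthetic choices on physiological
#' grounds (breathing grows more regular with non-REM depth; REM is
#' irregular); see the package vignette.
#'
#' @return A data frame with one row per stage (row names = stage) and
#'   columns `stage`, `breath_freq_mean` (Hz), `breath_freq_sd` (Hz),
#'   `amp_mean` (V), `amp_sd` (V), `breath_period_cv`, `breath_amp_cv`.
#' @export
#' @examples
#' default_stage_models()
default_stage_models <- function() {
  m <- data.frame(
    stage            = stage_levels(),
    breath_freq_mean = c(0.272, 0.264, 0.233, 0.210, 0.292),
    breath_freq_sd   = c(0.006, 0.005, 0.005, 0.004, 0.015),
    amp_mean         = 7.89 * c(1.0, 0.9, 0.8, 0.7, 1.0),
    amp_sd           = c(0.25, 0.22, 0.20, 0.17, 0.70),
    breath_period_cv = c(0.03, 0.03, 0.02, 0.02, 0.12),
    breath_amp_cv    = c(0.05, 0.05, 0.04, 0.04, 0.15),
    stringsAsFactors = FALSE)
  rownames(m) <- m$stage
  m
}

check_stage_model <- function(model) {
  model <- as.list(model)
  need <- c("breath_freq_mean", "breath_freq_sd", "amp_mean", "amp_sd",
            "breath_period_cv", "breath_amp_cv")
  miss <- setdiff(need, names(model))
  if (length(miss))
    stop_respstage(paste("stage model lacks field(s):", paste(miss, collapse = ", ")),
                   "respstage_invalid_parameter")
  if (model$breath_freq_mean <= 0 || model$breath_freq_mean > 1)
    stop_respstage("breath_freq_mean must lie in (0, 1] Hz", "respstage_invalid_parameter")
  if (model$amp_mean <= 0)
    stop_respstage("amp_mean must be positive", "respstage_invalid_parameter")
  if (any(unlist(model[c("breath_freq_sd", "amp_sd", "breath_period_cv",
                         "breath_amp_cv")]) < 0))
    stop_respstage("dispersion parameters must be non-negative", "respstage_invalid_parameter")
  model
}

# Unit breath waveform on phase u in [0, 1): linear rise to the plateau
# (film approaching then in contact with the electrode during exhalation),
# then linear fall back to baseline during inhalation; any remaining phase
# fraction rests at 0 V.
breath_waveform <- function(u, rise_frac = 0.25, plateau_frac = 0.25,
                            fall_frac = 1 - rise_frac - plateau_frac) {
  v <- numeric(length(u))
  r <- rise_frac; p <- plateau_frac; f <- fall_frac
  if (r > 0) { i <- u < r;                 v[i] <- u[i] / r }
  i <- u >= r & u < r + p;                 v[i] <- 1
  if (f > 0) { i <- u >= r + p & u < r + p + f; v[i] <- 1 - (u[i] - r - p) / f }
  v
}

#' Synthesize a single breath cycle
#'
#' One cycle of the sensor's breath waveform: a linear rise to a voltage
#' plateau while the dielectric film is in contact during exhalation, then
#' a linear fall back to 0 V during inhalation.
#'
#' @param period breath period in seconds (> `dt`).
#' @param amplitude plateau voltage in volts (>= 0); 7.89 V is the normal
#'   nasal-breath default elsewhere in the package.
#' @param dt sampling interval in seconds.
#' @param rise_frac,plateau_frac fractions of the period spent rising and
#'   at the plateau; together with the implicit fall fraction
#'   `1 - rise_frac - plateau_frac` they must not exceed 1.
#' @return A [resp_trace()] of `round(period / dt)` samples.
#' @export
#' @examples
#' cyc <- synth_breath_cycle(period = 4, amplitude = 7.89)
#' max(cyc$samples)
synth_breath_cycle <- function(period, amplitude, dt = 0.017,
                               rise_frac = 0.25, plateau_frac = 0.25) {
  if (!is.finite(period) || period <= 0 || !is.finite(dt) || dt <= 0)
    stop_respstage("period and dt must be positive", "respstage_invalid_parameter")
  if (period <= dt)
    stop_respstage("period must exceed the sampling interval", "respstage_invalid_parameter")
  if (amplitude < 0)
    stop_respstage("amplitude must be non-negative", "respstage_invalid_parameter")
  if (rise_frac < 0 || plateau_frac < 0 || rise_frac + plateau_frac > 1)
    stop_respstage("rise_frac + plateau_frac must lie in [0, 1]", "respstage_invalid_parameter")
  n <- round(period / dt)
  u <- (seq_len(n) - 1) * dt / period
  resp_trace(amplitude * breath_waveform(u, rise_frac, plateau_frac), dt = dt)
}

# Draw from N(mean, sd) truncated to (lo, hi]; sd = 0 returns the clamped mean.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(min(max(mean, lo + .Machine$double.eps), hi), n))
  x <- stats::rnorm(n, mean, sd)
  for (i in which(x <= lo | x > hi)) {
    for (tries in 1:100) {
      x[i] <- stats::rnorm(1, mean, sd)
      if (x[i] > lo && x[i] <= hi) break
    }
    if (x[i] <= lo || x[i] > hi) x[i] <- min(max(mean, lo + 1e-12), hi)
  }
  x
}

# Draw the breath sequence (onsets, periods, amplitudes) covering `duration`
# seconds under a stage model. One epoch-level frequency and amplitude draw,
# then per-breath cv jitter.
draw_breaths <- function(model, duration) {
  f0 <- rnorm_trunc(1, model$breath_freq_mean, model$breath_freq_sd, 0.05, 1)
  a0 <- rnorm_trunc(1, model$amp_mean, model$amp_sd, 0)
  n_guess <- ceiling(duration * f0 * 1.5) + 5L
  periods <- numeric(0); amps <- numeric(0); total <- 0
  while (total < duration) {
    fj <- f0 * (1 + stats::rnorm(n_guess, 0, model$breath_period_cv))
    fj <- pmin(pmax(fj, 0.05), 1)
    aj <- pmax(a0 * (1 + stats::rnorm(n_guess, 0, model$breath_amp_cv)), 0)
    periods <- c(periods, 1 / fj); amps <- c(amps, aj)
    total <- sum(periods)
  }
  onsets <- cumsum(c(0, periods))
  keep <- onsets[-length(onsets)] < duration
  list(onsets = onsets[c(keep, FALSE)], periods = periods[keep], amps = amps[keep])
}

# Evaluate the breath sequence at uniform sample times.
breaths_to_samples <- function(breaths, duration, dt,
                               rise_frac = 0.25, plateau_frac = 0.25) {
  n <- round(duration / dt)
  t <- (seq_len(n) - 1) * dt
  k <- findInterval(t, breaths$onsets)
  u <- (t - breaths$onsets[k]) / breaths$periods[k]
  list(t = t, k = k, u = pmin(u, 1),
       v = breaths$amps[k] * breath_waveform(pmin(u, 1), rise_frac, plateau_frac))
}

#' Synthesize a stage-conditioned respiration epoch
#'
#' Generates a 30-s (by default) mask-sensor voltage epoch for one sleep
#' stage: breath-by-breath trapezoid cycles whose frequency and amplitude
#' are drawn from the stage model. One epoch-level frequency draw
#' `N(breath_freq_mean, breath_freq_sd)` (truncated to (0.05, 1] Hz) sets
#' the epoch's dominant frequency; per-breath jitter with coefficients of
#' variation `breath_period_cv` / `breath_amp_cv` adds cycle-to-cycle
#' irregularity (large for REM).
#'
#' @param model one row of [default_stage_models()] (or a list with the
#'   same fields).
#' @param duration epoch length in seconds; must cover at least one mean
#'   breath period.
#' @param dt sampling interval in seconds (default 0.017 s, i.e. 1765
#'   samples per 30 s).
#' @param seed integer seed for reproducible draws; `NULL` uses the current
#'   RNG stream.
#' @param rise_frac,plateau_frac breath waveform shape, see
#'   [synth_breath_cycle()].
#' @return A [resp_trace()] of `round(duration / dt)` samples labelled with
#'   the model's stage.
#' @export
#' @examples
#' m <- default_stage_models()["AWAKE", ]
#' ep <- synth_epoch(m, duration = 30, seed = 1)
#' ep
synth_epoch <- function(model, duration = 30, dt = 0.017, seed = NULL,
                        rise_frac = 0.25, plateau_frac = 0.25) {
  model <- check_stage_model(model)
  if (!is.finite(duration) || duration < 1 / model$breath_freq_mean)
    stop_respstage("duration must cover at least one mean breath period",
                   "respstage_invalid_parameter")
  with_seed(seed, {
    br <- draw_breaths(model, duration)
    s <- breaths_to_samples(br, duration, dt, rise_frac, plateau_frac)
    resp_trace(s$v, dt = dt, stage = model$stage)
  })
}

#' Synthesize a snoring epoch
#'
#' Same breath envelope as [synth_epoch()] (identical draws for identical
#' seeds), but with the amplitude attenuated (the airway obstruction of a
#' snore lowers the generated output) and a high-frequency vibration
#' multiplied onto the exhalation segments of each breath, giving the
#' characteristic vibrating snore waveform.
#'
#' @inheritParams synth_epoch
#' @param vib_freq snore vibration frequency in Hz; must be at least 5x the
#'   model's breath frequency.
#' @param vib_depth vibration modulation depth in \[0, 1\].
#' @param attenuation multiplicative amplitude attenuation in (0, 1\].
#' @return A [resp_trace()].
#' @export
synth_snoring_epoch <- function(model, vib_freq = 8, vib_depth = 0.5,
                                attenuation = 0.6, duration = 30, dt = 0.017,
                                seed = NULL, rise_frac = 0.25,
                                plateau_frac = 0.25) {
  model <- check_stage_model(model)
  if (vib_freq < 5 * model$breath_freq_mean)
    stop_respstage("vib_freq must be at least 5x the breath frequency",
                   "respstage_invalid_parameter")
  if (vib_depth < 0 || vib_depth > 1)
    stop_respstage("vib_depth must lie in [0, 1]", "respstage_invalid_parameter")
  if (attenuation <= 0 || attenuation > 1)
    stop_respstage("attenuation must lie in (0, 1]", "respstage_invalid_parameter")
  if (!is.finite(duration) || duration < 1 / model$breath_freq_mean)
    stop_respstage("duration must cover at least one mean breath period",
                   "respstage_invalid_parameter")
  with_seed(seed, {
    br <- draw_breaths(model, duration)
    s <- breaths_to_samples(br, duration, dt, rise_frac, plateau_frac)
    v <- attenuation * s$v
    exhal <- s$u < rise_frac + plateau_frac  # film in contact: airflow out
    v[exhal] <- v[exhal] * (1 + vib_depth * sin(2 * pi * vib_freq * s$t[exhal]))
    resp_trace(v, dt = dt, stage = model$stage)
  })
}

#' Add acquisition artifacts to a trace
#'
#' Emulates the acquisition chain: a constant DC offset (the bias
#' introduced by the microcontroller's analog front end) plus white
#' Gaussian measurement noise.
#'
#' @param trace a [resp_trace()].
#' @param dc_offset constant offset in volts (default 2.5 V, the mid-rail
#'   bias of a 5 V acquisition board).
#' @param noise_sd per-sample Gaussian noise standard deviation in volts.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return A [resp_trace()] with modified samples.
#' @export
add_acquisition_artifacts <- function(trace, dc_offset = 2.5, noise_sd = 0.05,
                                      seed = NULL) {
  if (noise_sd < 0)
    stop_respstage("noise_sd must be non-negative", "respstage_invalid_parameter")
  with_seed(seed, {
    noise <- if (noise_sd > 0) stats::rnorm(length(trace$samples), 0, noise_sd) else 0
    resp_trace(trace$samples + dc_offset + noise, dt = trace$dt,
               start_time = trace$start_time, stage = trace$stage)
  })
}

#' Synthesize a whole sleep session
#'
#' Generates time-contiguous epochs following a hypnogram, each via
#' [synth_epoch()] followed by [add_acquisition_artifacts()]. Epoch `i`
#' derives its seed as `seed + i`, so sessions are reproducible while
#' epochs stay independent.
#'
#' @param hypnogram data frame with columns `stage` and `duration_s`
#'   (one row per epoch, in time order).
#' @param models per-stage model table, see [default_stage_models()].
#' @param dc_offset,noise_sd acquisition artifact parameters, see
#'   [add_acquisition_artifacts()].
#' @param dt sampling interval in seconds.
#' @param seed integer base seed.
#' @return An object of class `sleep_session`: list with `epochs` (list of
#'   [resp_trace()]) and `hypnogram` (data frame `start_s`, `duration_s`,
#'   `stage`).
#' @export
#' @examples
#' hyp <- data.frame(stage = c("AWAKE", "N3"), duration_s = c(60, 60))
#' ses <- synth_session(hyp, seed = 1)
#' ses
synth_session <- function(hypnogram, models = default_stage_models(),
                          dc_offset = 2.5, noise_sd = 0.05, dt = 0.017,
                          seed = 1) {
  if (is.null(hypnogram) || nrow(hypnogram) == 0L)
    stop_respstage("hypnogram must contain at least one epoch",
                   "respstage_invalid_parameter")
  if (any(hypnogram$duration_s <= 0))
    stop_respstage("epoch durations must be positive", "respstage_invalid_parameter")
  stages <- as.character(as_stage(hypnogram$stage))
  starts <- cumsum(c(0, hypnogram$duration_s))[seq_len(nrow(hypnogram))]
  epochs <- vector("list", nrow(hypnogram))
  for (i in seq_len(nrow(hypnogram))) {
    model <- models[stages[i], ]
    epochs[[i]] <- with_seed(if (is.null(seed)) NULL else seed + i, {
      tr <- synth_epoch(model, duration = hypnogram$duration_s[i], dt = dt,
                        seed = NULL)
      add_acquisition_artifacts(tr, dc_offset = dc_offset, noise_sd = noise_sd,
                                seed = NULL)
    })
    epochs[[i]]$start_time <- starts[i]
  }
  structure(list(epochs = epochs,
                 hypnogram = data.frame(start_s = starts,
                                        duration_s = hypnogram$duration_s,
                                        stage = as_stage(stages))),
            class = "sleep_session")
}

#' @export
print.sleep_session <- function(x, ...) {
  cat(sprintf("<sleep_session> %d epochs, %.0f s total\n",
              length(x$epochs), sum(x$hypnogram$duration_s)))
  print(table(x$hypnogram$stage))
  invisible(x)
}

#' Concatenate a session's epochs into one trace
#'
#' @param session a `sleep_session`.
#' @return A single [resp_trace()] covering the whole session.
#' @export
session_trace <- function(session) {
  resp_trace(unlist(lapply(session$epochs, `[[`, "samples")),
             dt = session$epochs[[1]]$dt,
             start_time = session$epochs[[1]]$start_time)
}
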