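test_that("default stage models carry the observed per-stage structure", {
  m <- default_stage_models()
  expect_setequal(m$stage, stage_levels())
  expect_equal(m["AWAKE", "breath_freq_mean"], 0.272)
  expect_equal(m["N1", "breath_freq_mean"], 0.264)
  expect_equal(m["N2", "breath_freq_mean"], 0.233)
  expect_equal(m["N3", "breath_freq_mean"], 0.210)
  expect_equal(m["REM", "breath_freq_mean"], 0.292)
  # amplitude weakens monotonically through the non-REM depths
  amps <- m[c("AWAKE", "N1", "N2", "N3"), "amp_mean"]
  expect_true(all(diff(amps) < 0))
  # REM is the irregular stage: largest dispersion everywhere
  expect_true(all(m["REM", "breath_freq_sd"] > m[m$stage != "REM", "breath_freq_sd"]))
  expect_true(all(m["REM", "breath_amp_cv"] > m[m$stage != "REM", "breath_amp_cv"]))
})

test_that("a single breath cycle is a rise-plateau-fall pulse", {
  z <- synth_breath_cycle(period = 1, amplitude = 0, dt = 0.017)
  expect_true(all(z$samples == 0))

  cyc <- synth_breath_cycle(period = 4, amplitude = 7.89, dt = 0.017)
  expect_length(cyc$samples, round(4 / 0.017))
  expect_equal(max(cyc$samples), 7.89)
  expect_identical(cyc$samples[1], 0)
  # waveform returns to baseline at the cycle end (within one sample's slope)
  expect_lt(abs(cyc$samples[length(cyc$samples)]), 7.89 * 2 * 0.017 / 4 / 0.5)

  cyc2 <- synth_breath_cycle(period = 2, amplitude = 1, dt = 0.017,
                             rise_frac = 0.25, plateau_frac = 0.25)
  u <- (seq_along(cyc2$samples) - 1) * 0.017 / 2
  plateau <- u >= 0.25 & u < 0.5
  expect_true(any(plateau))
  expect_true(all(abs(cyc2$samples[plateau] - 1) < 1e-12))

  expect_error(synth_breath_cycle(period = -1, amplitude = 1),
               class = "respstage_invalid_parameter")
  expect_error(synth_breath_cycle(period = 1, amplitude = 1, dt = 0),
               class = "respstage_invalid_parameter")
  expect_error(synth_breath_cycle(period = 1, amplitude = 1, rise_frac = 0.8,
                                  plateau_frac = 0.5),
               class = "respstage_invalid_parameter")
})

test_that("synth_epoch is seeded, stage-labeled and of round(duration/dt) length", {
  m <- default_stage_models()["N2", ]
  ep1 <- synth_epoch(m, duration = 30, dt = 0.017, seed = 7)
  ep2 <- synth_epoch(m, duration = 30, dt = 0.017, seed = 7)
  ep3 <- synth_epoch(m, duration = 30, dt = 0.017, seed = 8)
  expect_identical(ep1$samples, ep2$samples)
  expect_false(identical(ep1$samples, ep3$samples))
  expect_length(ep1$samples, 1765)
  expect_identical(ep1$stage, "N2")
  expect_error(synth_epoch(m, duration = 1), class = "respstage_invalid_parameter")
})

test_that("a zero-variance epoch is exactly periodic at the model frequency", {
  f <- 0.272
  ep <- synth_epoch(noiseless_model(freq = f), duration = 30, dt = 0.017, seed = 1)
  # independent closed-form oracle: every sample equals the piecewise
  # trapezoid evaluated at its phase within the exact 1/f breath grid
  t <- (seq_along(ep$samples) - 1) * 0.017
  phase <- (t %% (1 / f)) * f
  expected <- 7.89 * ifelse(phase < 0.25, phase / 0.25,
                     ifelse(phase < 0.5, 1, 1 - (phase - 0.5) / 0.5))
  expect_lt(max(abs(ep$samples - expected)), 1e-9)
  # cycle count over the epoch matches the planted frequency
  expect_equal(dominant_frequency(remove_offset(ep)), f, tolerance = 0.01)
})

test_that("epoch statistics recover the generating model", {
  m <- default_stage_models()["AWAKE", ]
  rates <- vapply(1:200, function(s) {
    ep <- remove_offset(synth_epoch(m, duration = 30, seed = s))
    respiration_rate(dominant_frequency(ep))
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 60 * m$breath_freq_mean), 3 * se)
})

test_that("REM has the largest across-epoch respiration-rate dispersion", {
  models <- default_stage_models()
  sds <- vapply(stage_levels(), function(s) {
    rates <- vapply(1:40, function(i) {
      ep <- remove_offset(synth_epoch(models[s, ], duration = 30,
                                      seed = 1000 + i))
      respiration_rate(dominant_frequency(ep))
    }, numeric(1))
    stats::sd(rates)
  }, numeric(1))
  expect_true(all(sds["REM"] > sds[setdiff(stage_levels(), "REM")]))
})

test_that("snoring epochs attenuate and vibrate the breath envelope", {
  m <- default_stage_models()["N2", ]
  base <- synth_epoch(m, duration = 30, seed = 3)
  degenerate <- synth_snoring_epoch(m, vib_freq = 8, vib_depth = 0,
                                    attenuation = 1, duration = 30, seed = 3)
  expect_equal(degenerate$samples, base$samples, tolerance = 1e-12)

  att <- synth_snoring_epoch(m, vib_freq = 8, vib_depth = 0, attenuation = 0.6,
                             duration = 30, seed = 3)
  expect_equal(max(att$samples), 0.6 * max(base$samples), tolerance = 1e-12)

  # the vibration plants a secondary spectral peak near vib_freq
  snore <- synth_snoring_epoch(m, vib_freq = 8, vib_depth = 0.5,
                               attenuation = 0.6, duration = 30, seed = 3)
  power_near <- function(tr, f0, half = 0.5) {
    n <- 2^15
    mag <- Mod(stats::fft(c(tr$samples - mean(tr$samples),
                            numeric(n - length(tr$samples)))))
    freqs <- (seq_len(n) - 1) / (n * tr$dt)
    max(mag[freqs >= f0 - half & freqs <= f0 + half])
  }
  expect_gt(power_near(snore, 8), 5 * power_near(base, 8))

  expect_error(synth_snoring_epoch(m, vib_freq = 0.3, duration = 30),
               class = "respstage_invalid_parameter")
  expect_error(synth_snoring_epoch(m, vib_freq = 8, vib_depth = 2, duration = 30),
               class = "respstage_invalid_parameter")
})

test_that("acquisition artifacts add a DC offset plus seeded noise", {
  ep <- synth_epoch(noiseless_model(), duration = 30, seed = 1)
  expect_identical(add_acquisition_artifacts(ep, dc_offset = 0, noise_sd = 0)$samples,
                   ep$samples)
  zero <- resp_trace(numeric(100), dt = 0.017)
  expect_true(all(add_acquisition_artifacts(zero, dc_offset = 1.2,
                                            noise_sd = 0)$samples == 1.2))
  shifted <- add_acquisition_artifacts(ep, dc_offset = 2.5, noise_sd = 0)
  expect_lt(abs(mean(shifted$samples) - mean(ep$samples) - 2.5), 1e-12)
  n1 <- add_acquisition_artifacts(ep, dc_offset = 2.5, noise_sd = 0.05, seed = 4)
  n2 <- add_acquisition_artifacts(ep, dc_offset = 2.5, noise_sd = 0.05, seed = 4)
  expect_identical(n1$samples, n2$samples)
})

test_that("synth_session builds contiguous labeled epochs deterministically", {
  hyp1 <- data.frame(stage = "N1", duration_s = 60)
  s1 <- synth_session(hyp1, seed = 2)
  expect_length(s1$epochs, 1)
  expect_identical(s1$epochs[[1]]$stage, "N1")

  hyp5 <- data.frame(stage = stage_levels(), duration_s = 30)
  a <- synth_session(hyp5, seed = 5)
  b <- synth_session(hyp5, seed = 5)
  expect_identical(lapply(a$epochs, `[[`, "samples"),
                   lapply(b$epochs, `[[`, "samples"))
  expect_equal(a$hypnogram$start_s, c(0, 30, 60, 90, 120))

  # awake epochs carry larger breath peaks than deep sleep
  hyp2 <- data.frame(stage = c("AWAKE", "N3"), duration_s = c(60, 60))
  ses <- synth_session(hyp2, noise_sd = 0, seed = 9)
  pk <- vapply(ses$epochs,
               function(e) peak_output_voltage(remove_offset(e)), numeric(1))
  expect_gt(pk[1], pk[2])

  expect_error(synth_session(data.frame(stage = character(0),
                                        duration_s = numeric(0))),
               class = "respstage_invalid_parameter")
})
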