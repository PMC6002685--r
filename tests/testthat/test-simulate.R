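# Synthetic-data primitives: oscillators, line noise, suppression dynamics.

test_that("oscillator spectrum peaks at the specified frequency and level", {
  w <- simulate_soae_waveform(oscillator_spec(2000, -5), duration = 30,
                              sample_rate = 44100, calibration_db = 30,
                              seed = 1)
  sp <- baseline_spectrum(w, fmax = 4000)
  top <- sp[which.max(sp$level_db), ]
  expect_lt(abs(top$frequency_hz - 2000), 2 + 1e-9)
  expect_lt(abs(top$level_db - (-5)), 0.5)
})

test_that("jittered oscillators stay near their center frequency", {
  spec <- oscillator_spec(3000, -4, frequency_jitter_sd = 2,
                          amplitude_jitter_sd = 0.5)
  w <- simulate_soae_waveform(spec, 10, 44100, seed = 4)
  sp <- baseline_spectrum(w, fmax = 4000)
  top <- sp[which.max(sp$level_db), ]
  expect_lt(abs(top$frequency_hz - 3000), 25)
})

test_that("silent oscillator (level -Inf) yields an all-zero waveform", {
  w <- simulate_soae_waveform(oscillator_spec(2000, -Inf), 1, 44100,
                              seed = 1)
  expect_identical(w$samples, numeric(44100))
})

test_that("waveform synthesis is bit-identical given the same seed", {
  spec <- oscillator_spec(2000, -5, frequency_jitter_sd = 1,
                          amplitude_jitter_sd = 0.3)
  w1 <- simulate_soae_waveform(spec, 1, 44100, seed = 7)
  w2 <- simulate_soae_waveform(spec, 1, 44100, seed = 7)
  expect_identical(w1$samples, w2$samples)
})

test_that("oscillator frequency above the supported band is rejected", {
  expect_error(simulate_soae_waveform(oscillator_spec(20000, -5), 1, 44100),
               "too low")
})

test_that("line noise places peaks at exact harmonics of the fundamental", {
  w <- simulate_line_noise(60, 1:3, c(-5, -10, -12), duration = 30,
                           sample_rate = 44100, seed = 2)
  sp <- baseline_spectrum(w, fmax = 300)
  for (f in c(60, 120, 180)) {
    near <- sp[abs(sp$frequency_hz - f) <= 10, ]
    expect_equal(near$frequency_hz[which.max(near$level_db)], f)
  }
  # 18th harmonic lands at 1080 Hz, inside the emission band
  w18 <- simulate_line_noise(60, 18, -10, duration = 30, seed = 2)
  sp18 <- baseline_spectrum(w18, fmax = 2000)
  expect_equal(sp18$frequency_hz[which.max(sp18$level_db)], 1080)
})

test_that("line noise rejects empty harmonic sets and super-Nyquist tones", {
  expect_error(simulate_line_noise(60, integer(0), numeric(0)),
               "at least one harmonic")
  expect_error(simulate_line_noise(60, 400, -10, sample_rate = 44100),
               "Nyquist")
})

test_that("suppression envelope follows the stated first-order dynamics", {
  ev <- make_events(1)
  spec <- suppression_spec(magnitude = 1, onset_latency = 0.01,
                           time_constant = 0.025)
  fs <- 1000
  g <- suppression_envelope(spec, ev, duration = 10, sample_rate = fs)
  t_idx <- function(t) round(t * fs) + 1L
  on <- ev$speech_onset_s + spec$onset_latency
  # deep into the speech sound the envelope sits at the asymptote
  expect_equal(g[t_idx(on + 0.4)], -1, tolerance = 1e-6)
  # one time constant after effective onset: -(1 - exp(-1)) * magnitude
  expect_equal(g[t_idx(on + spec$time_constant)], -(1 - exp(-1)),
               tolerance = 1e-2)
  # before the trial the envelope is exactly zero
  expect_identical(g[seq_len(t_idx(ev$trial_onset_s))], numeric(t_idx(ev$trial_onset_s)))
})

test_that("suppression envelope degenerate cases", {
  spec <- suppression_spec(1)
  expect_identical(suppression_envelope(spec, make_events(0), 1, 100),
                   numeric(100))
  # zero magnitude integrates to exactly zero
  g0 <- suppression_envelope(suppression_spec(0), make_events(3), 20, 100)
  expect_identical(sum(g0), 0)
  # overlapping speech periods are rejected
  ev <- make_events(2, period = 0.3)
  expect_error(suppression_envelope(spec, ev, 5, 100), "overlap")
})

test_that("noise floor realises its target per-bin spectrum level", {
  w <- simulate_noise_floor(-25, duration = 60, seed = 3)
  sp <- baseline_spectrum(w, fmax = 8000)
  med <- median(sp$level_db[sp$frequency_hz > 1000])
  expect_lt(abs(med - (-25)), 1)
})
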