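# Shared fixtures and independent oracles for the test suite.

# Bare peak-table row(s) for filter and measurement tests.
make_peaks <- function(frequency_hz, baseline_level_db = -5) {
  tibble::tibble(
    frequency_hz = frequency_hz,
    baseline_level_db = baseline_level_db,
    snr_db = 20,
    stability_sd_db = NA_real_,
    fail_stability = FALSE,
    fail_line_noise = FALSE,
    excluded_by = "none"
  )
}

# Event table with the canonical trial timing: 1.5 s lead-in, 0.5 s speech,
# trials every `period` seconds starting at `start`.
make_events <- function(n_trials, start = 2, period = 5,
                        subject_id = "S001") {
  onset <- start + (seq_len(n_trials) - 1) * period
  tibble::tibble(
    subject_id = subject_id, trial_index = seq_len(n_trials),
    block = 1L, trial_onset_s = onset, speech_onset_s = onset + 1.5,
    syllable = "ba", response = "ba"
  )
}

# Independent single-bin DFT oracle: direct O(n) sums at chosen bins with
# the same Hamming window and zero-padding convention as the pipeline, but
# no FFT. Returns levels in dB under the calibration.
dft_oracle_level <- function(samples, frame, bins, params, calibration_db) {
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(params$window - 1)) /
                           (params$window - 1))
  s0 <- (frame - 1) * params$hop
  x <- samples[(s0 + 1):(s0 + params$window)] * w
  n <- 0:(params$window - 1)
  sapply(bins, function(k) {
    ph <- -2 * pi * k * n / params$n_fft
    mag <- Mod(sum(x * complex(real = cos(ph), imaginary = sin(ph))))
    20 * log10(max(mag * 2 / sum(w), 1e-10)) + calibration_db
  })
}

# Analytic window-convolution oracle for the expected stimulus-window delta:
# per frame, the level offset implied by Hamming-weighting the linear-
# amplitude gain envelope; averaged over frames whose centers fall in the
# 500-ms stimulus window. Independent of the STFT implementation.
envelope_delta_oracle <- function(gain_db, events, params,
                                  window_duration = 0.5) {
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(params$window - 1)) /
                           (params$window - 1))
  nf <- (length(gain_db) - params$window) %/% params$hop + 1
  centers <- ((seq_len(nf) - 1) * params$hop + params$window / 2) /
    params$sample_rate
  per_trial <- sapply(seq_len(nrow(events)), function(i) {
    fr <- which(centers >= events$speech_onset_s[i] &
                  centers < events$speech_onset_s[i] + window_duration)
    mean(sapply(fr, function(f) {
      s0 <- (f - 1) * params$hop
      20 * log10(sum(w * 10^(gain_db[(s0 + 1):(s0 + params$window)] / 20)) /
                   sum(w))
    }))
  })
  mean(per_trial)
}

# Small, fast cohort configuration used across statistical tests.
reduced_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_mono = 4, n_early = 4, n_late = 4, n_trials = 40,
         n_blocks = 10, seed = seed),
    list(...))
  do.call(cohort_config, args)
}

# One subject per injected magnitude; no covariate effects so every subject
# carries exactly `magnitude` dB of suppression. Audio-path cohort.
fixed_magnitude_config <- function(magnitude, seed, n_subjects = 3,
                                   n_trials = 40) {
  cohort_config(
    n_mono = n_subjects, n_early = 0, n_late = 0, n_trials = n_trials,
    n_blocks = 10, baseline_duration_s = 2,
    mu_suppression = magnitude, b_control = 0, b_wm = 0,
    b_interaction = 0, b_group = 0, residual_sd = 0,
    freq_jitter_sd = 0, amp_jitter_sd = 0, seed = seed
  )
}
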