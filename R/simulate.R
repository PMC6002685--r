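#' Oscillator specification for a synthetic SOAE
#'
#' Describes one spontaneous emission as a narrowband oscillator: a sinusoid
#' with optional slow Ornstein--Uhlenbeck frequency wander and slow
#' amplitude (dB) wander. This amplitude-stabilised model is deliberately
#' simpler than a full limit-cycle (van der Pol) oscillator; it is sufficient
#' to exercise spectral detection and ±25 Hz peak tracking, which is what the
#' synthetic cohorts exist to validate.
#'
#' @param frequency Center frequency in Hz (emissions typically fall between
#'   1 and 10 kHz).
#' @param level Target baseline spectrum level in dB SPL. `-Inf` yields a
#'   silent (all-zero) oscillator.
#' @param frequency_jitter_sd Stationary SD of the slow frequency wander, Hz.
#'   Keep well below the 25 Hz tracking half-width.
#' @param amplitude_jitter_sd Stationary SD of the slow level wander, dB.
#' @return An object of class `oscillator_spec`.
#' @export
#' @examples
#' oscillator_spec(2000, -5)
oscillator_spec <- function(frequency, level, frequency_jitter_sd = 0,
                            amplitude_jitter_sd = 0) {
  stopifnot(frequency > 0, frequency_jitter_sd >= 0, amplitude_jitter_sd >= 0)
  if (!(is.finite(level) || (is.infinite(level) && level < 0)))
    stop("oscillator level must be finite or -Inf")
  structure(list(frequency = frequency, level = level,
                 frequency_jitter_sd = frequency_jitter_sd,
                 amplitude_jitter_sd = amplitude_jitter_sd),
            class = "oscillator_spec")
}

#' Suppression specification
#'
#' Parameters of the injected efferent suppression: the asymptotic level
#' reduction during contralateral stimulation, the neural onset latency, and
#' the exponential time constant of both onset and recovery. Contralateral
#' MOC effects on emission level develop on a fast time scale (tens of
#' milliseconds), which the defaults reflect.
#'
#' @param magnitude Asymptotic level reduction in dB (non-negative).
#' @param onset_latency Delay between stimulus onset and the start of the
#'   gain change, seconds.
#' @param time_constant Exponential time constant of onset and recovery,
#'   seconds (must be positive).
#' @return An object of class `suppression_spec`.
#' @export
suppression_spec <- function(magnitude = 1, onset_latency = 0.010,
                             time_constant = 0.025) {
  stopifnot(magnitude >= 0, onset_latency >= 0, time_constant > 0)
  structure(list(magnitude = magnitude, onset_latency = onset_latency,
                 time_constant = time_constant),
            class = "suppression_spec")
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Ornstein-Uhlenbeck sample path with stationary sd, simulated on a coarse
# grid and linearly interpolated to n samples. sd = 0 gives zeros cheaply.
ou_path <- function(n, sample_rate, sd, tau, coarse_rate = 200) {
  if (sd == 0 || n == 0L) return(numeric(n))
  dt <- 1 / coarse_rate
  m <- max(2L, ceiling(n / sample_rate * coarse_rate) + 1L)
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  z <- rnorm(m, sd = innov_sd)
  z[1] <- rnorm(1, sd = sd)
  x <- as.numeric(stats::filter(z, a, method = "recursive"))
  stats::approx(x = seq_len(m) - 1, y = x,
                xout = (seq_len(n) - 1) / sample_rate * coarse_rate,
                rule = 2)$y
}

#' Synthesize an SOAE waveform
#'
#' Generates a narrowband oscillation whose long-window spectrum peaks at
#' `spec$frequency` (within one analysis bin) and at `spec$level` (within
#' 0.5 dB) under the given calibration constant. Deterministic given `seed`.
#'
#' @param spec An [oscillator_spec()].
#' @param duration Duration in seconds (> 0).
#' @param sample_rate Sampling rate in Hz; must be at least 2.5 times the
#'   oscillator frequency.
#' @param calibration_db Calibration constant (dB SPL of a full-scale
#'   sinusoid).
#' @param seed Integer seed for the jitter processes.
#' @return An [ear_recording()].
#' @export
#' @examples
#' w <- simulate_soae_waveform(oscillator_spec(2000, -5), duration = 1,
#'                             sample_rate = 44100, seed = 1)
simulate_soae_waveform <- function(spec, duration, sample_rate = 44100,
                                   calibration_db = 30, seed = 1) {
  stopifnot(inherits(spec, "oscillator_spec"), duration > 0)
  if (sample_rate < 2.5 * spec$frequency)
    stop(sprintf(
      "sample_rate %g Hz too low for a %g Hz oscillator (need >= %g Hz)",
      sample_rate, spec$frequency, 2.5 * spec$frequency))
  n <- round(duration * sample_rate)
  amp <- level_to_amplitude(spec$level, calibration_db)
  if (amp == 0) return(ear_recording(numeric(n), sample_rate, calibration_db))
  with_rng_seed(seed, {
    f_jit <- ou_path(n, sample_rate, spec$frequency_jitter_sd, tau = 1)
    a_jit <- ou_path(n, sample_rate, spec$amplitude_jitter_sd, tau = 5)
    phase0 <- runif(1, 0, 2 * pi)
    phase <- phase0 + 2 * pi * cumsum(spec$frequency + f_jit) / sample_rate
    x <- amp * 10^(a_jit / 20) * sin(phase)
    ear_recording(x, sample_rate, calibration_db)
  })
}

#' Synthesize mains line noise
#'
#' A sum of sinusoids at integer multiples of the mains fundamental, each at
#' a stated level. Harmonics of 60 Hz can masquerade as emission peaks, which
#' is what the line-noise exclusion filter exists to remove.
#'
#' @param fundamental Mains fundamental in Hz (default 60).
#' @param harmonics Integer vector of harmonic numbers (k >= 1); peaks appear
#'   at `k * fundamental`.
#' @param levels Level in dB SPL for each harmonic (same length as
#'   `harmonics`).
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param calibration_db Calibration constant.
#' @param seed Integer seed (random phases).
#' @return An [ear_recording()].
#' @export
simulate_line_noise <- function(fundamental = 60, harmonics = 1:3,
                                levels = rep(-10, length(harmonics)),
                                duration = 1, sample_rate = 44100,
                                calibration_db = 30, seed = 1) {
  harmonics <- as.integer(harmonics)
  if (length(harmonics) < 1L) stop("need at least one harmonic")
  stopifnot(all(harmonics >= 1L), length(levels) == length(harmonics))
  freqs <- harmonics * fundamental
  if (any(freqs >= sample_rate / 2))
    stop(sprintf("harmonic at %g Hz is at or above Nyquist (%g Hz)",
                 max(freqs), sample_rate / 2))
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  with_rng_seed(seed, {
    x <- numeric(n)
    for (i in seq_along(freqs)) {
      a <- level_to_amplitude(levels[i], calibration_db)
      x <- x + a * sin(2 * pi * freqs[i] * t + runif(1, 0, 2 * pi))
    }
    ear_recording(x, sample_rate, calibration_db)
  })
}

#' Efferent gain envelope over a trial sequence
#'
#' Per-sample gain trace in dB implementing first-order efferent dynamics:
#' 0 dB outside stimulation; starting `onset_latency` after each speech
#' onset the gain decays exponentially toward `-magnitude` with the spec's
#' time constant, and recovers toward 0 (same latency and time constant)
#' after speech offset.
#'
#' @param spec A [suppression_spec()].
#' @param events Trial-event table with column `speech_onset_s` (seconds);
#'   events must be sorted and non-overlapping. An empty table gives an
#'   all-zero trace.
#' @param duration Trace duration in seconds.
#' @param sample_rate Samples per second of the trace.
#' @param speech_duration Duration of each speech sound in seconds.
#' @return Numeric vector of gains in dB, length `round(duration *
#'   sample_rate)`.
#' @export
suppression_envelope <- function(spec, events, duration, sample_rate,
                                 speech_duration = 0.5) {
  stopifnot(inherits(spec, "suppression_spec"), duration > 0)
  n <- round(duration * sample_rate)
  g <- numeric(n)
  if (is.null(events) || nrow(events) == 0L || spec$magnitude == 0)
    return(g)
  on <- sort(events$speech_onset_s) + spec$onset_latency
  off <- on + speech_duration
  if (any(diff(on) < speech_duration))
    stop("events overlap: speech periods must be disjoint")

  # piecewise exponential relaxation toward alternating targets
  bounds <- c(rbind(on, off), duration)
  targets <- c(rbind(rep(-spec$magnitude, length(on)), rep(0, length(on))), 0)
  t0 <- 0
  g0 <- 0
  tau <- spec$time_constant
  for (i in seq_along(bounds)) {
    t1 <- bounds[i]
    if (t1 > t0) {
      i0 <- floor(t0 * sample_rate) + 1L
      i1 <- min(n, ceiling(t1 * sample_rate))
      if (i1 >= i0) {
        tt <- (seq.int(i0, i1) - 1) / sample_rate
        seg_target <- if (i == 1L) 0 else targets[i - 1L]
        idx <- tt >= t0 & tt < t1
        g[seq.int(i0, i1)[idx]] <-
          seg_target + (g0 - seg_target) * exp(-(tt[idx] - t0) / tau)
      }
      seg_target <- if (i == 1L) 0 else targets[i - 1L]
      g0 <- seg_target + (g0 - seg_target) * exp(-(t1 - t0) / tau)
      t0 <- t1
    }
  }
  g
}

#' Gaussian noise floor
#'
#' White Gaussian noise whose expected per-bin spectrum level (at the
#' package's default STFT parameters) equals `floor_level` dB SPL. With a
#' Hamming window of length `L` and amplitude normalisation `2/sum(w)`, a
#' white process with per-sample SD `sigma` has expected per-bin power
#' `sigma^2 * sum(w^2) * (2/sum(w))^2`, which this function inverts.
#'
#' @param floor_level Target per-bin spectrum level in dB SPL.
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz.
#' @param calibration_db Calibration constant.
#' @param window_length STFT window length the floor level refers to.
#' @param seed Integer seed.
#' @return An [ear_recording()].
#' @export
simulate_noise_floor <- function(floor_level = -25, duration = 1,
                                 sample_rate = 44100, calibration_db = 30,
                                 window_length = 16384, seed = 1) {
  w <- hamming_window(window_length)
  # per-bin amplitude^2 of unit-sd noise under the package normalisation
  unit_gain <- sum(w^2) * (2 / sum(w))^2
  target_amp2 <- level_to_amplitude(floor_level, calibration_db)^2
  sigma <- sqrt(target_amp2 / unit_gain)
  n <- round(duration * sample_rate)
  with_rng_seed(seed, ear_recording(rnorm(n, sd = sigma), sample_rate,
                                    calibration_db))
}
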