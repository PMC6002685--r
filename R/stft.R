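#' STFT parameters
#'
#' Parameters of the short-time Fourier transform used throughout the
#' pipeline. The defaults are a 22,050-point transform of Hamming-windowed,
#' zero-padded 16,384-sample frames advancing by 4,096 samples at a 44.1 kHz
#' sampling rate, giving a bin spacing of exactly
#' `sample_rate / n_fft = 2 Hz`.
#'
#' @param n_fft Transform length in points; frames are zero-padded to this
#'   length.
#' @param window Hamming window length in points (must not exceed `n_fft`).
#' @param hop Hop size in points (must not exceed `window`).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `stft_params` with derived fields
#'   `bin_spacing` (Hz) and `n_bins`.
#' @export
#' @examples
#' stft_params()$bin_spacing  # 2 Hz
stft_params <- function(n_fft = 22050, window = 16384, hop = 4096,
                        sample_rate = 44100) {
  stopifnot(n_fft >= 1, window >= 1, hop >= 1)
  if (window > n_fft) stop("window length must not exceed n_fft")
  if (hop > window) stop("hop must not exceed window length")
  structure(list(n_fft = as.integer(n_fft), window = as.integer(window),
                 hop = as.integer(hop), sample_rate = sample_rate,
                 bin_spacing = sample_rate / n_fft,
                 n_bins = as.integer(floor(n_fft / 2) + 1L)),
            class = "stft_params")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Frame layout: frame i (1-based) covers samples [(i-1)*hop + 1, (i-1)*hop +
# window]; its timestamp is the window center ((i-1)*hop + window/2) / fs.
n_frames_for <- function(n_samples, params) {
  if (n_samples < params$window) return(0L)
  as.integer((n_samples - params$window) %/% params$hop + 1L)
}

frame_center_times <- function(frames, params) {
  ((frames - 1) * params$hop + params$window / 2) / params$sample_rate
}

# Frame indices whose center time lies in [t_start, t_end)
frames_in_window <- function(t_start, t_end, n_frames, params) {
  ctr <- function(i) ((i - 1) * params$hop + params$window / 2) /
    params$sample_rate
  lo <- ceiling((t_start * params$sample_rate - params$window / 2) /
                  params$hop + 1)
  lo <- max(1L, as.integer(lo))
  out <- integer(0)
  i <- lo
  while (i <= n_frames && ctr(i) < t_end) {
    if (ctr(i) >= t_start) out <- c(out, i)
    i <- i + 1L
  }
  out
}

#' Short-time Fourier transform
#'
#' Hamming-windowed, zero-padded, hopped magnitude spectrogram with levels in
#' dB SPL under the recording's calibration constant. Frame magnitudes are
#' normalised by `2 / sum(window)` so that a sinusoid of amplitude `a` on a
#' bin reads `20*log10(a) + calibration_db`; normalised magnitudes are
#' clipped at 1e-10 (-200 dB re full scale) before the log so silent input
#' yields finite levels.
#'
#' @param recording An [ear_recording()].
#' @param params An [stft_params()]; its `sample_rate` must match the
#'   recording.
#' @param frames Optional integer vector of 1-based frame indices to compute
#'   (default: all frames). Useful when only a few analysis windows are
#'   needed from a long recording.
#' @param fmax Optional upper frequency bound; bins above it are dropped.
#' @return An object of class `soae_spectrogram`: list with `times` (frame
#'   center times, s), `frequencies` (Hz), `levels` (frames x bins matrix,
#'   dB SPL), `frames`, `params`, `calibration_db`.
#' @export
stft <- function(recording, params = stft_params(), frames = NULL,
                 fmax = NULL) {
  stopifnot(inherits(recording, "ear_recording"),
            inherits(params, "stft_params"))
  if (!isTRUE(all.equal(recording$sample_rate, params$sample_rate)))
    stop("recording sample rate does not match STFT parameters")
  n <- length(recording$samples)
  if (n < params$window)
    stop(sprintf(
      "recording too short for one analysis window: %d samples, need >= %d",
      n, params$window))
  nf <- n_frames_for(n, params)
  if (is.null(frames)) frames <- seq_len(nf)
  frames <- as.integer(frames)
  stopifnot(all(frames >= 1L), all(frames <= nf))

  freqs <- (seq_len(params$n_bins) - 1) * params$bin_spacing
  keep_bins <- if (is.null(fmax)) seq_len(params$n_bins) else
    which(freqs <= fmax)
  w <- hamming_window(params$window)
  norm <- 2 / sum(w)

  levels <- matrix(NA_real_, nrow = length(frames), ncol = length(keep_bins))
  chunk <- 64L
  for (start in seq(1L, length(frames), by = chunk)) {
    idx <- frames[start:min(length(frames), start + chunk - 1L)]
    seg <- matrix(0, nrow = params$n_fft, ncol = length(idx))
    for (j in seq_along(idx)) {
      s0 <- (idx[j] - 1L) * params$hop
      seg[seq_len(params$window), j] <-
        recording$samples[(s0 + 1L):(s0 + params$window)] * w
    }
    mag <- Mod(stats::mvfft(seg))[keep_bins, , drop = FALSE] * norm
    levels[start:(start + length(idx) - 1L), ] <-
      t(amplitude_to_level(mag, recording$calibration_db))
  }

  structure(list(times = frame_center_times(frames, params),
                 frequencies = freqs[keep_bins], levels = levels,
                 frames = frames, params = params,
                 calibration_db = recording$calibration_db),
            class = "soae_spectrogram")
}

#' @export
print.soae_spectrogram <- function(x, ...) {
  cat(sprintf("<soae_spectrogram> %d frames x %d bins, %.1f-%.1f Hz\n",
              nrow(x$levels), ncol(x$levels), min(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.soae_spectrogram <- function(x, ...) {
  tibble::tibble(
    frame = rep(x$frames, times = length(x$frequencies)),
    time_s = rep(x$times, times = length(x$frequencies)),
    frequency_hz = rep(x$frequencies, each = length(x$times)),
    level_db = as.vector(x$levels)
  )
}

#' Frame-averaged baseline spectrum
#'
#' Averages STFT frames of a quiet baseline recording (canonically ~3 min)
#' into a single spectrum suitable for emission peak picking. Averaging is
#' done in the power domain across frames and converted to dB afterwards,
#' which is unbiased for stationary signals; frames are streamed so long
#' recordings never materialise a full spectrogram.
#'
#' @param recording An [ear_recording()].
#' @param params An [stft_params()].
#' @param fmax Optional upper frequency bound for the returned spectrum.
#' @return A tibble of class `soae_spectrum` with columns `frequency_hz` and
#'   `level_db`; attributes carry the calibration, parameters and frame
#'   count.
#' @export
baseline_spectrum <- function(recording, params = stft_params(),
                              fmax = NULL) {
  stopifnot(inherits(recording, "ear_recording"))
  n <- length(recording$samples)
  if (n < params$window)
    stop(sprintf(
      "recording too short for one analysis window: %d samples, need >= %d",
      n, params$window))
  nf <- n_frames_for(n, params)
  freqs <- (seq_len(params$n_bins) - 1) * params$bin_spacing
  keep_bins <- if (is.null(fmax)) seq_len(params$n_bins) else
    which(freqs <= fmax)
  w <- hamming_window(params$window)
  norm <- 2 / sum(w)

  acc <- numeric(length(keep_bins))
  chunk <- 64L
  for (start in seq(1L, nf, by = chunk)) {
    idx <- start:min(nf, start + chunk - 1L)
    seg <- matrix(0, nrow = params$n_fft, ncol = length(idx))
    for (j in seq_along(idx)) {
      s0 <- (idx[j] - 1L) * params$hop
      seg[seq_len(params$window), j] <-
        recording$samples[(s0 + 1L):(s0 + params$window)] * w
    }
    mag <- Mod(stats::mvfft(seg))[keep_bins, , drop = FALSE] * norm
    acc <- acc + rowSums(mag^2)
  }
  out <- tibble::tibble(
    frequency_hz = freqs[keep_bins],
    level_db = amplitude_to_level(sqrt(acc / nf), recording$calibration_db)
  )
  class(out) <- c("soae_spectrum", class(out))
  attr(out, "calibration_db") <- recording$calibration_db
  attr(out, "params") <- params
  attr(out, "n_frames") <- nf
  out
}
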