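#' Ear-canal recording object
#'
#' A lightweight container for a single-channel ear-canal waveform together
#' with its sample rate, ear label, and the calibration constant that maps
#' full-scale digital amplitude to sound pressure level. Throughout the
#' package, the level in dB SPL of a sinusoid with digital amplitude `a` is
#' `20*log10(a) + calibration_db`; every spectrum the package produces is
#' expressed on that scale.
#'
#' @param samples Numeric vector of waveform samples (full-scale units,
#'   nominally in `[-1, 1]` but not clipped).
#' @param sample_rate Sampling rate in Hz.
#' @param calibration_db Calibration constant in dB: the level in dB SPL of a
#'   full-scale (amplitude 1) sinusoid.
#' @param ear Ear label, `"left"` or `"right"` (or `NA` if not applicable).
#'
#' @return An object of class `ear_recording`.
#' @export
#' @examples
#' w <- ear_recording(sin(2 * pi * 1000 * (0:999) / 44100), 44100)
#' duration(w)
ear_recording <- function(samples, sample_rate, calibration_db = 30,
                          ear = NA_character_) {
  stopifnot(is.numeric(samples), length(samples) > 0L,
            is.numeric(sample_rate), sample_rate > 0,
            is.finite(calibration_db))
  if (!is.na(ear)) ear <- match.arg(ear, c("left", "right"))
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         calibration_db = calibration_db, ear = ear),
    class = "ear_recording"
  )
}

#' @export
print.ear_recording <- function(x, ...) {
  cat(sprintf("<ear_recording> %.2f s @ %g Hz, ear = %s, calibration = %g dB\n",
              duration(x), x$sample_rate, x$ear, x$calibration_db))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x An `ear_recording`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "ear_recording"))
  length(x$samples) / x$sample_rate
}

#' @export
length.ear_recording <- function(x) length(x$samples)

# dB SPL <-> full-scale amplitude under a calibration constant
level_to_amplitude <- function(level_db, calibration_db) {
  ifelse(is.infinite(level_db) & level_db < 0, 0,
         10^((level_db - calibration_db) / 20))
}

amplitude_to_level <- function(amplitude, calibration_db) {
  20 * log10(pmax(amplitude, 1e-10)) + calibration_db
}
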