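#' Average tracked-peak level over a measurement window
#'
#' Tracks the emission peak (±`halfwidth` Hz of its baseline frequency) in
#' every STFT frame whose center time lies in `[t_start, t_start +
#' duration)` and averages the per-frame dB levels arithmetically. Frames
#' with no trackable local maximum are dropped; at least `min_frames` usable
#' frames are required, otherwise the measurement is returned as missing
#' with a machine-readable reason.
#'
#' @param spectrogram A `soae_spectrogram` from [stft()] (it may contain only
#'   the frames needed, e.g. when computed with the `frames` argument).
#' @param soae_frequency Baseline emission frequency, Hz.
#' @param t_start Window start, seconds.
#' @param duration Window duration, seconds (the canonical measurement
#'   window is 500 ms).
#' @param halfwidth Peak-tracking half-width, Hz.
#' @param min_frames Minimum usable frames per window.
#' @return One-row tibble: `level_db`, `n_frames`, `missing_reason` (`NA`
#'   when the measurement succeeded).
#' @export
window_average_level <- function(spectrogram, soae_frequency, t_start,
                                 duration = 0.5, halfwidth = 25,
                                 min_frames = 3) {
  stopifnot(inherits(spectrogram, "soae_spectrogram"))
  t_end <- t_start + duration
  span <- range(spectrogram$times)
  if (t_end <= span[1] - 1e-9 || t_start > span[2] + 1e-9)
    stop(sprintf(
      "measurement window [%.3f, %.3f) lies outside the spectrogram (frames span %.3f-%.3f s)",
      t_start, t_end, span[1], span[2]))
  rows <- which(spectrogram$times >= t_start & spectrogram$times < t_end)
  if (!length(rows))
    return(tibble::tibble(level_db = NA_real_, n_frames = 0L,
                          missing_reason = "no_frames_in_window"))
  lv <- vapply(rows, function(r)
    track_peak_core(spectrogram$frequencies, spectrogram$levels[r, ],
                    soae_frequency, halfwidth)[2], numeric(1))
  lv <- lv[!is.na(lv)]
  if (length(lv) < min_frames)
    return(tibble::tibble(level_db = NA_real_, n_frames = length(lv),
                          missing_reason = "too_few_tracked_frames"))
  tibble::tibble(level_db = mean(lv), n_frames = length(lv),
                 missing_reason = NA_character_)
}

#' Per-trial suppression measurement for one emission
#'
#' The trial's suppression is the difference, in dB, between the average
#' tracked-peak level over the 500-ms window beginning at speech onset and
#' the average over the 500-ms window ending at trial onset (the 1,500-ms
#' silent lead-in separates the two). Negative values indicate suppression.
#'
#' @param spectrogram A `soae_spectrogram` covering both windows.
#' @param soae_frequency Baseline emission frequency, Hz.
#' @param event One-row trial event (needs `trial_index`, `trial_onset_s`,
#'   `speech_onset_s`).
#' @param window_duration Measurement window duration, seconds.
#' @param halfwidth Peak-tracking half-width, Hz.
#' @param min_frames Minimum usable frames per window.
#' @return One-row tibble: `trial_index`, `soae_frequency_hz`,
#'   `baseline_level_db`, `stimulus_level_db`, `delta_db`,
#'   `n_frames_baseline`, `n_frames_stimulus`, `missing_reason`.
#' @export
trial_delta <- function(spectrogram, soae_frequency, event,
                        window_duration = 0.5, halfwidth = 25,
                        min_frames = 3) {
  # a window wholly outside the recording is an error at the single-window
  # level, but at the trial level it becomes a flagged missing row
  wal <- function(t_start) {
    tryCatch(
      window_average_level(spectrogram, soae_frequency, t_start,
                           window_duration, halfwidth, min_frames),
      error = function(e)
        tibble::tibble(level_db = NA_real_, n_frames = 0L,
                       missing_reason = "window_outside_recording"))
  }
  base <- wal(event$trial_onset_s - window_duration)
  stim <- wal(event$speech_onset_s)
  reason <- dplyr::coalesce(base$missing_reason, stim$missing_reason)
  tibble::tibble(
    trial_index = event$trial_index,
    soae_frequency_hz = soae_frequency,
    baseline_level_db = base$level_db,
    stimulus_level_db = stim$level_db,
    delta_db = stim$level_db - base$level_db,
    n_frames_baseline = base$n_frames,
    n_frames_stimulus = stim$n_frames,
    missing_reason = reason
  )
}

#' Measure suppression for every trial and surviving emission
#'
#' Computes one suppression measurement per (trial x surviving emission)
#' from a task recording. Only the STFT frames whose centers fall in some
#' measurement window are transformed, so hour-long recordings are handled
#' without materialising a full spectrogram.
#'
#' @param recording Task-phase [ear_recording()] from the test ear.
#' @param events Trial-event tibble (columns `trial_index`, `trial_onset_s`,
#'   `speech_onset_s`).
#' @param peaks Filtered peak table; only rows with `excluded_by == "none"`
#'   are measured.
#' @param params An [stft_params()].
#' @param window_duration,halfwidth,min_frames See [trial_delta()].
#' @return Tibble with one row per (trial, emission); rows that could not be
#'   measured carry `NA` levels and a `missing_reason`. Empty (with a
#'   warning) when no emission survives the filters.
#' @export
measure_trials <- function(recording, events, peaks,
                           params = stft_params(), window_duration = 0.5,
                           halfwidth = 25, min_frames = 3) {
  stopifnot(inherits(recording, "ear_recording"), is.data.frame(events))
  surv <- peaks[peaks$excluded_by == "none", , drop = FALSE]
  empty <- tibble::tibble(
    trial_index = integer(), soae_frequency_hz = double(),
    baseline_level_db = double(), stimulus_level_db = double(),
    delta_db = double(), n_frames_baseline = integer(),
    n_frames_stimulus = integer(), missing_reason = character())
  if (nrow(surv) == 0L) {
    warning("no surviving SOAEs; returning empty measurement table")
    return(empty)
  }
  if (nrow(events) == 0L) return(empty)

  nf <- n_frames_for(length(recording$samples), params)
  needed <- unique(unlist(lapply(seq_len(nrow(events)), function(i) {
    c(frames_in_window(events$trial_onset_s[i] - window_duration,
                       events$trial_onset_s[i], nf, params),
      frames_in_window(events$speech_onset_s[i],
                       events$speech_onset_s[i] + window_duration, nf,
                       params))
  })))
  needed <- sort(needed)
  if (!length(needed)) {
    return(purrr::map_dfr(seq_len(nrow(events)), function(i)
      tibble::tibble(
        trial_index = events$trial_index[i],
        soae_frequency_hz = surv$frequency_hz,
        baseline_level_db = NA_real_, stimulus_level_db = NA_real_,
        delta_db = NA_real_, n_frames_baseline = 0L,
        n_frames_stimulus = 0L,
        missing_reason = "window_outside_recording")))
  }
  spg <- stft(recording, params, frames = needed,
              fmax = max(surv$frequency_hz) + 2 * halfwidth)

  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    purrr::map_dfr(surv$frequency_hz, function(f0)
      trial_delta(spg, f0, ev, window_duration, halfwidth, min_frames))
  })
}
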