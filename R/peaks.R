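#' Detect candidate SOAE peaks in a baseline spectrum
#'
#' An emission candidate is a local spectral maximum that exceeds a
#' median-smoothed estimate of the noise floor by at least `snr_threshold`
#' dB within `[fmin, fmax]`. When two candidates lie within `min_separation`
#' Hz of each other only the higher is retained. (No universal detection
#' criterion exists for spontaneous emissions; these defaults follow common
#' OAE practice and are fully configurable.)
#'
#' @param spectrum A spectrum as returned by [baseline_spectrum()]: a data
#'   frame with columns `frequency_hz` and `level_db` on a uniform grid.
#' @param snr_threshold Minimum height above the smoothed floor, dB.
#' @param fmin,fmax Frequency band searched, Hz.
#' @param floor_bandwidth Bandwidth of the running-median floor estimate, Hz.
#' @param min_separation Minimum distance between retained peaks, Hz
#'   (inclusive: candidates at exactly this distance are merged).
#' @return A tibble with one row per candidate, sorted by frequency:
#'   `frequency_hz`, `baseline_level_db`, `snr_db`, `stability_sd_db` (NA
#'   until [stability_filter()] runs), `fail_stability`, `fail_line_noise`,
#'   `excluded_by`.
#' @export
detect_soae_candidates <- function(spectrum, snr_threshold = 6,
                                   fmin = 500, fmax = 12000,
                                   floor_bandwidth = 200,
                                   min_separation = 10) {
  stopifnot(is.data.frame(spectrum),
            all(c("frequency_hz", "level_db") %in% names(spectrum)),
            fmin < fmax)
  f <- spectrum$frequency_hz
  lv <- spectrum$level_db
  binw <- stats::median(diff(f))
  k <- max(3L, 2L * as.integer(floor_bandwidth / binw / 2) + 1L)
  k <- min(k, 2L * (length(lv) %/% 2L) - 1L)
  floor_est <- stats::runmed(lv, k, endrule = "median")

  n <- length(lv)
  is_max <- c(FALSE, lv[2:(n - 1)] > lv[1:(n - 2)] &
                lv[2:(n - 1)] >= lv[3:n], FALSE)
  cand <- which(is_max & (lv - floor_est) >= snr_threshold &
                  f >= fmin & f <= fmax)
  # minimum-separation merge: keep the higher of any pair within range
  cand <- cand[order(lv[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(f[i] - f[kept]) > min_separation))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  out <- tibble::tibble(
    frequency_hz = f[kept],
    baseline_level_db = lv[kept],
    snr_db = (lv - floor_est)[kept],
    stability_sd_db = NA_real_,
    fail_stability = FALSE,
    fail_line_noise = FALSE,
    excluded_by = "none"
  )
  out
}

# Recompute the single exclusion label from the independent failure flags so
# that the two filters commute: stability takes precedence in the label, but
# the flags record both outcomes.
update_exclusion <- function(peaks) {
  peaks$excluded_by <- dplyr::case_when(
    peaks$fail_stability ~ "stability",
    peaks$fail_line_noise ~ "line_noise",
    TRUE ~ "none"
  )
  peaks
}

#' Level-stability exclusion filter
#'
#' Measures each candidate's level in each of the first four non-overlapping
#' 30-s segments of the baseline recording and excludes emissions whose
#' sample SD across the four segments exceeds 6 dB (strictly: a peak with SD
#' exactly 6 dB is kept). Only exclusion flags are modified; frequencies and
#' levels are untouched.
#'
#' @param peaks Candidate table from [detect_soae_candidates()].
#' @param baseline The baseline [ear_recording()] (>= 120 s). Ignored when
#'   `segment_levels` is supplied.
#' @param params An [stft_params()].
#' @param threshold Exclusion threshold in dB (exceedance is strict).
#' @param halfwidth Half-width of the per-segment peak search window, Hz.
#' @param segment_levels Optional numeric matrix (peaks x segments) of
#'   pre-measured segment levels, bypassing the recording (used for exact
#'   boundary fixtures and by callers that already hold segment spectra).
#' @param segment_duration Segment duration in seconds.
#' @param n_segments Number of segments.
#' @return `peaks` with `stability_sd_db` filled in and exclusion flags
#'   updated.
#' @export
stability_filter <- function(peaks, baseline = NULL, params = stft_params(),
                             threshold = 6, halfwidth = 25,
                             segment_levels = NULL, segment_duration = 30,
                             n_segments = 4) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0L) return(update_exclusion(peaks))
  if (is.null(segment_levels)) {
    stopifnot(inherits(baseline, "ear_recording"))
    need <- n_segments * segment_duration
    if (duration(baseline) < need)
      stop(sprintf("baseline too short for stability filter: %.1f s, need >= %g s",
                   duration(baseline), need))
    seg_n <- round(segment_duration * baseline$sample_rate)
    segment_levels <- matrix(NA_real_, nrow(peaks), n_segments)
    for (s in seq_len(n_segments)) {
      seg <- ear_recording(
        baseline$samples[((s - 1) * seg_n + 1):(s * seg_n)],
        baseline$sample_rate, baseline$calibration_db, baseline$ear)
      spec <- baseline_spectrum(seg, params,
                                fmax = max(peaks$frequency_hz) + 2 * halfwidth)
      for (p in seq_len(nrow(peaks))) {
        win <- abs(spec$frequency_hz - peaks$frequency_hz[p]) <= halfwidth
        segment_levels[p, s] <- max(spec$level_db[win])
      }
    }
  }
  stopifnot(nrow(segment_levels) == nrow(peaks))
  peaks$stability_sd_db <- apply(segment_levels, 1, stats::sd, na.rm = TRUE)
  peaks$fail_stability <- !is.na(peaks$stability_sd_db) &
    peaks$stability_sd_db > threshold
  update_exclusion(peaks)
}

#' Line-noise exclusion filter
#'
#' Excludes peaks lying within `tolerance` Hz (inclusive) of any integer
#' multiple of the mains fundamental, since such peaks may be generated or
#' contaminated by electrical interference. Only exclusion flags are
#' modified.
#'
#' @param peaks Candidate table.
#' @param tolerance Distance to the nearest multiple at or under which a
#'   peak is excluded, Hz.
#' @param fundamental Mains fundamental, Hz.
#' @return `peaks` with exclusion flags updated.
#' @export
#' @examples
#' p <- tibble::tibble(frequency_hz = c(1068, 1080), baseline_level_db = -5,
#'                     snr_db = 15, stability_sd_db = NA_real_,
#'                     fail_stability = FALSE, fail_line_noise = FALSE,
#'                     excluded_by = "none")
#' line_noise_filter(p)$excluded_by  # "none", "line_noise"
line_noise_filter <- function(peaks, tolerance = 5, fundamental = 60) {
  stopifnot(is.data.frame(peaks), tolerance >= 0, fundamental > 0)
  if (nrow(peaks) == 0L) return(update_exclusion(peaks))
  k <- round(peaks$frequency_hz / fundamental)
  dist <- abs(peaks$frequency_hz - k * fundamental)
  peaks$fail_line_noise <- dist <= tolerance
  update_exclusion(peaks)
}

#' Select the test ear
#'
#' The ear retained for task recordings is the one with more surviving
#' (unexcluded) emissions between 1,000 and 10,000 Hz. Ties go to the right
#' ear (the tally counts only in-range, unexcluded peaks).
#'
#' @param left_peaks,right_peaks Filtered peak tables for each ear.
#' @param range Frequency range counted, Hz (inclusive).
#' @param tie Ear chosen on a tie.
#' @return `"left"` or `"right"`, with attribute `counts`.
#' @export
select_test_ear <- function(left_peaks, right_peaks,
                            range = c(1000, 10000), tie = "right") {
  tally <- function(p) {
    if (is.null(p) || nrow(p) == 0L) return(0L)
    sum(p$excluded_by == "none" &
          p$frequency_hz >= range[1] & p$frequency_hz <= range[2])
  }
  nl <- tally(left_peaks)
  nr <- tally(right_peaks)
  if (nl == 0L && nr == 0L)
    stop("no surviving SOAEs in either ear; subject must be excluded")
  ear <- if (nl > nr) "left" else if (nr > nl) "right" else tie
  structure(ear, counts = c(left = nl, right = nr))
}

#' Track an emission peak within a spectrum slice
#'
#' Finds the highest local maximum within `halfwidth` Hz (inclusive) of the
#' baseline emission frequency in a single spectrum (one STFT frame or an
#' averaged spectrum). Returns a missing measurement when no local maximum
#' exists in the window (e.g. the spectrum is strictly monotonic there).
#'
#' @param spectrum Data frame with `frequency_hz` and `level_db`, or a
#'   `soae_spectrogram` together with `frame`.
#' @param baseline_frequency Baseline emission frequency, Hz.
#' @param halfwidth Search half-width, Hz (inclusive window).
#' @param frame Frame index (row of the spectrogram) when `spectrum` is a
#'   `soae_spectrogram`.
#' @return One-row tibble with `frequency_hz` and `level_db` (both `NA` when
#'   no local maximum is found).
#' @export
track_peak <- function(spectrum, baseline_frequency, halfwidth = 25,
                       frame = NULL) {
  if (inherits(spectrum, "soae_spectrogram")) {
    stopifnot(!is.null(frame))
    f <- spectrum$frequencies
    lv <- spectrum$levels[frame, ]
  } else {
    f <- spectrum$frequency_hz
    lv <- spectrum$level_db
  }
  res <- track_peak_core(f, lv, baseline_frequency, halfwidth)
  tibble::tibble(frequency_hz = res[1], level_db = res[2])
}

# Returns c(frequency, level) or c(NA, NA). Local maxima are evaluated with
# neighbours drawn from just outside the window where available, so a
# maximum sitting exactly on the window edge still counts (inclusive
# boundary).
track_peak_core <- function(f, lv, f0, halfwidth) {
  in_win <- which(f >= f0 - halfwidth & f <= f0 + halfwidth)
  if (!length(in_win)) return(c(NA_real_, NA_real_))
  lo <- max(1L, min(in_win) - 1L)
  hi <- min(length(f), max(in_win) + 1L)
  idx <- lo:hi
  lvs <- lv[idx]
  m <- length(idx)
  if (m < 3L) return(c(NA_real_, NA_real_))
  loc <- which(lvs[2:(m - 1)] > lvs[1:(m - 2)] &
                 lvs[2:(m - 1)] >= lvs[3:m]) + 1L
  cand <- idx[loc]
  cand <- cand[cand %in% in_win]
  if (!length(cand)) return(c(NA_real_, NA_real_))
  best <- cand[which.max(lv[cand])]
  c(f[best], lv[best])
}
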