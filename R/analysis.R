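#' Run the full suppression analysis on a cohort
#'
#' Sequences the complete pipeline on a cohort with audio: per subject,
#' baseline spectra for both ears, emission detection, the stability and
#' line-noise exclusion filters, test-ear selection, per-trial suppression
#' measurement on the task recording, then composite construction and the
#' three statistical models (cognitive, group, residualized group).
#' Subjects with no surviving emissions are excluded and logged, not fatal.
#'
#' @param cohort A `soae_cohort` with waveforms ([simulate_cohort()] with
#'   `audio = TRUE`, or [read_cohort()]), or a dataset directory path.
#' @param params An [stft_params()].
#' @param snr_threshold,fmin,fmax,min_separation Detection settings, see
#'   [detect_soae_candidates()].
#' @param stability_threshold Stability exclusion threshold, dB.
#' @param line_tolerance,line_fundamental Line-noise exclusion settings, Hz.
#' @param halfwidth Peak-tracking half-width, Hz.
#' @param window_duration Measurement window, seconds.
#' @param min_frames Minimum usable frames per window.
#' @param fit_models Fit the statistical models (requires both language
#'   groups with measurable subjects).
#' @return An object of class `soae_analysis`: list with `peaks` (all ears,
#'   all subjects), `test_ears`, `measurements`, `metadata` (with recomputed
#'   composites), `fits` (`cognitive`, `group`, `group_resid`), `excluded`
#'   (tibble of excluded subjects and reasons), and `counts` (per-stage
#'   tallies).
#' @export
run_cohort_analysis <- function(cohort, params = stft_params(),
                                snr_threshold = 6, fmin = 500, fmax = 12000,
                                min_separation = 10,
                                stability_threshold = 6,
                                line_tolerance = 5, line_fundamental = 60,
                                halfwidth = 25, window_duration = 0.5,
                                min_frames = 3, fit_models = TRUE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "soae_cohort"))
  if (is.null(cohort$waves))
    stop("cohort has no audio; use simulate_cohort(audio = TRUE), ",
         "read_cohort(), or the measurement-level path ",
         "simulate_trial_measurements()")

  md <- cohort$metadata
  all_peaks <- list()
  measurements <- list()
  excluded <- list()
  test_ears <- character(nrow(md))
  names(test_ears) <- md$subject_id

  for (i in seq_len(nrow(md))) {
    s <- md$subject_id[i]
    w <- cohort$waves[[s]]
    ear_peaks <- list()
    for (ear in c("left", "right")) {
      rec <- w[[paste0("baseline_", ear)]]
      if (is.null(rec)) next
      spec <- baseline_spectrum(rec, params, fmax = fmax + 200)
      pk <- detect_soae_candidates(spec, snr_threshold, fmin, fmax,
                                   min_separation = min_separation)
      pk <- stability_filter(pk, rec, params, stability_threshold,
                             halfwidth)
      pk <- line_noise_filter(pk, line_tolerance, line_fundamental)
      pk <- dplyr::bind_cols(tibble::tibble(subject_id = s, ear = ear), pk)
      ear_peaks[[ear]] <- pk
    }
    subj_peaks <- dplyr::bind_rows(ear_peaks)
    all_peaks[[s]] <- subj_peaks

    ear <- tryCatch(
      select_test_ear(ear_peaks$left, ear_peaks$right),
      error = function(e) NA_character_)
    test_ears[s] <- as.character(ear)
    if (is.na(ear)) {
      excluded[[s]] <- tibble::tibble(subject_id = s,
                                      reason = "no_surviving_soaes")
      next
    }
    if (is.null(w$task)) {
      excluded[[s]] <- tibble::tibble(subject_id = s,
                                      reason = "no_task_recording")
      next
    }
    surv <- subj_peaks[subj_peaks$ear == ear, , drop = FALSE]
    ev <- cohort$events[cohort$events$subject_id == s, , drop = FALSE]
    m <- measure_trials(w$task, ev, surv, params, window_duration,
                        halfwidth, min_frames)
    if (nrow(m))
      m <- dplyr::bind_cols(tibble::tibble(subject_id = s), m["trial_index"],
                            m[setdiff(names(m), c("subject_id",
                                                  "trial_index"))])
    measurements[[s]] <- m
  }

  peaks <- dplyr::bind_rows(all_peaks)
  empty_meas <- tibble::tibble(
    subject_id = character(), trial_index = integer(),
    soae_frequency_hz = double(), baseline_level_db = double(),
    stimulus_level_db = double(), delta_db = double(),
    n_frames_baseline = integer(), n_frames_stimulus = integer(),
    missing_reason = character())
  meas <- dplyr::bind_rows(c(list(empty_meas), unname(measurements)))
  excl <- dplyr::bind_rows(c(
    list(tibble::tibble(subject_id = character(), reason = character())),
    unname(excluded)))
  md2 <- add_composites(md)
  md2$test_ear <- unname(test_ears[md2$subject_id])

  fits <- NULL
  if (fit_models && nrow(meas)) {
    ok <- is.na(meas$missing_reason)
    mok <- meas[ok, , drop = FALSE]
    test_peaks <- peaks[peaks$excluded_by == "none" &
                          paste(peaks$subject_id, peaks$ear) %in%
                          paste(md2$subject_id, md2$test_ear), , drop = FALSE]
    fits <- list(
      cognitive = cognitive_model(mok, md2),
      group = group_model(mok, md2, peaks = test_peaks),
      group_resid = NULL
    )
    fits$group_resid <- residualized_group_model(fits$cognitive, md2)
  }

  counts <- tibble::tibble(
    subjects_in = nrow(md),
    subjects_excluded = nrow(excl),
    subjects_analyzed = nrow(md) - nrow(excl),
    soae_detected = nrow(peaks),
    soae_excluded_stability = sum(peaks$fail_stability),
    soae_excluded_line_noise = sum(peaks$fail_line_noise),
    rows_measured = nrow(meas),
    rows_missing = sum(!is.na(meas$missing_reason)),
    rows_modeled = if (is.null(fits)) 0L else
      length(stats::residuals(fits$cognitive$fit))
  )

  structure(list(peaks = peaks, test_ears = test_ears,
                 measurements = meas, metadata = md2, fits = fits,
                 excluded = excl, counts = counts),
            class = "soae_analysis")
}

#' @export
print.soae_analysis <- function(x, ...) {
  cat("<soae_analysis>\n")
  print(x$counts)
  if (!is.null(x$fits)) {
    cat("\nCognitive model:\n"); print(tidy(x$fits$cognitive))
    cat("\nGroup model:\n"); print(tidy(x$fits$group))
    cat("\nResidualized group model:\n"); print(tidy(x$fits$group_resid))
  }
  invisible(x)
}
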