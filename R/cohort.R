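#' Configuration of a synthetic cohort
#'
#' Bundles every parameter of the synthetic world: cohort composition, trial
#' structure, acoustics of the ear-canal recordings, and the generative model
#' tying each subject's suppression magnitude to their covariates.
#'
#' The suppression model works on the trial-delta (dB) scale. Each subject's
#' expected trial delta is
#' `-mu_suppression + b_control*C + b_wm*W + b_interaction*C*W +
#' b_group*is_bilingual + b_aoa*AoA*is_bilingual`, a subject-level residual
#' `N(0, residual_sd)` is added, and the injected suppression magnitude is
#' `max(0, -expected_delta)` (suppression cannot be negative). Negative
#' `b_control` therefore produces a negative fitted Control coefficient in
#' the trial-delta model, matching the sign conventions of the analysis the
#' package implements.
#'
#' @param n_mono,n_early,n_late Subjects per language group (monolingual,
#'   early bilingual, late bilingual).
#' @param n_trials,n_blocks Trials per subject and blocks (must divide
#'   evenly).
#' @param trial_lead_s Silent lead-in between trial onset and speech onset,
#'   seconds.
#' @param speech_duration_s Duration of each contralateral speech sound,
#'   seconds.
#' @param iti_s Silent gap after each speech sound before the next trial
#'   onset, seconds.
#' @param task_start_s Time of the first trial onset in the task recording,
#'   seconds.
#' @param baseline_duration_s Length of the quiet baseline recordings,
#'   seconds.
#' @param sample_rate,calibration_db Acoustic format of all recordings.
#' @param noise_floor_db Per-bin spectrum level of the white noise floor,
#'   dB SPL (the default sits ~20 dB below typical emission levels).
#' @param line_fundamental,line_harmonics,line_levels Mains interference:
#'   fundamental (Hz), harmonic numbers, and their levels (dB SPL).
#' @param soae_freq_range Frequency range emissions are drawn from, Hz.
#' @param soae_level_mean_mono,soae_level_mean_bi,soae_level_sd Baseline
#'   emission level distribution by group, dB SPL.
#' @param soae_count_probs Probabilities of 0,1,2,3,4 emissions per ear.
#' @param min_soae_separation Minimum spacing between a subject's emissions,
#'   Hz.
#' @param freq_jitter_sd,amp_jitter_sd Slow oscillator wander (Hz / dB); set
#'   to 0 for jitter-free validation cohorts.
#' @param prob_no_soae Probability that a subject has no emissions at all
#'   (emulating recruitment-stage exclusions).
#' @param mu_suppression Baseline suppression magnitude, dB.
#' @param b_control,b_wm,b_interaction,b_group,b_aoa,b_baseline_level Effect
#'   coefficients on the trial-delta scale (dB per unit predictor).
#' @param residual_sd Subject-level residual SD of suppression, dB.
#' @param trial_sd Trial-level measurement noise SD used by the fast
#'   (measurement-level) generator path, dB.
#' @param suppression_onset_latency,suppression_time_constant Efferent
#'   dynamics, seconds (see [suppression_spec()]).
#' @param group_task_shift Scale of group differences in the simulated task
#'   scores; 0 (default) keeps group orthogonal to the composites, 1 gives
#'   group mean differences of roughly the magnitude seen in mixed
#'   mono-/bilingual cohorts.
#' @param seed Integer RNG seed; every derived quantity is reproducible from
#'   it.
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(n_mono = 11, n_early = 11, n_late = 10,
                          n_trials = 240, n_blocks = 10,
                          trial_lead_s = 1.5, speech_duration_s = 0.5,
                          iti_s = 3.0, task_start_s = 2.0,
                          baseline_duration_s = 180,
                          sample_rate = 44100, calibration_db = 30,
                          noise_floor_db = -25,
                          line_fundamental = 60,
                          line_harmonics = c(1, 2, 3, 18),
                          line_levels = c(-5, -10, -12, -10),
                          soae_freq_range = c(1100, 6400),
                          soae_level_mean_mono = -4.9,
                          soae_level_mean_bi = -2.9,
                          soae_level_sd = 1.0,
                          soae_count_probs = c(0.18, 0.30, 0.28, 0.16, 0.08),
                          min_soae_separation = 80,
                          freq_jitter_sd = 1.0, amp_jitter_sd = 0.3,
                          prob_no_soae = 0,
                          mu_suppression = 1.0,
                          b_control = -0.30, b_wm = 0.30,
                          b_interaction = -0.10, b_group = -0.80,
                          b_aoa = 0, b_baseline_level = 0,
                          residual_sd = 0.25, trial_sd = 0.50,
                          suppression_onset_latency = 0.010,
                          suppression_time_constant = 0.025,
                          group_task_shift = 0,
                          seed = 1) {
  if (n_trials %% n_blocks != 0)
    stop("n_trials must be divisible by n_blocks")
  stopifnot(residual_sd >= 0, trial_sd >= 0, mu_suppression >= 0,
            length(line_levels) == length(line_harmonics),
            length(soae_count_probs) == 5L, prob_no_soae >= 0,
            prob_no_soae <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d mono + %d early + %d late bilingual, %d trials x %d blocks, seed %d\n",
    x$n_mono, x$n_early, x$n_late, x$n_trials, x$n_blocks, x$seed))
  invisible(x)
}

trial_period_s <- function(config) {
  config$trial_lead_s + config$speech_duration_s + config$iti_s
}

task_duration_s <- function(config) {
  config$task_start_s + config$n_trials * trial_period_s(config) + 1
}

# Group shifts applied to simulated task scores when group_task_shift = 1:
# bilinguals better on control-loaded tasks, monolinguals better on the
# (English) working-memory and vocabulary tasks.
task_group_shifts <- function() {
  list(
    mono     = c(vocabulary = 0.3, flanker = 0.0, working_memory = 0.5,
                 card_sort = 0.0, pattern = 0.0),
    late_bi  = c(vocabulary = -0.3, flanker = 0.5, working_memory = -0.5,
                 card_sort = 0.5, pattern = 0.5),
    early_bi = c(vocabulary = 0.0, flanker = 0.6, working_memory = 0.0,
                 card_sort = 0.6, pattern = 0.6)
  )
}

rnorm_clip <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

simulate_subject_table <- function(config) {
  groups <- c(rep("mono", config$n_mono), rep("early_bi", config$n_early),
              rep("late_bi", config$n_late))
  n <- length(groups)
  md <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    english_aoa = dplyr::case_when(
      groups == "mono" ~ rnorm_clip(n, 0.2, 0.4, 0, 3),
      groups == "early_bi" ~ rnorm_clip(n, 3.0, 1.9, 0, 6.9),
      TRUE ~ rnorm_clip(n, 9.1, 1.45, 7.1, 16)
    ),
    english_prof = dplyr::case_when(
      groups == "mono" ~ rnorm_clip(n, 9.8, 0.4, 0, 10),
      groups == "early_bi" ~ rnorm_clip(n, 9.4, 0.75, 0, 10),
      TRUE ~ rnorm_clip(n, 8.6, 1.0, 0, 10)
    ),
    korean_prof = dplyr::case_when(
      groups == "mono" ~ NA_real_,
      groups == "early_bi" ~ rnorm_clip(n, 8.1, 1.5, 0, 10),
      TRUE ~ rnorm_clip(n, 9.0, 1.0, 0, 10)
    )
  )
  shifts <- task_group_shifts()
  for (tk in nih_loadings()$task) {
    mu <- vapply(groups, function(g) shifts[[g]][[tk]], numeric(1)) *
      config$group_task_shift
    md[[tk]] <- rnorm(n, mean = mu, sd = 1)
  }
  add_composites(md)
}

# Draw emission frequencies avoiding line-noise exclusion zones (within
# 10 Hz of a mains multiple) and strong in-band harmonics, with a minimum
# mutual separation, so that detection completeness is well-defined.
draw_soae_frequencies <- function(n, config) {
  if (n == 0L) return(numeric(0))
  in_band_harm <- config$line_harmonics * config$line_fundamental
  in_band_harm <- in_band_harm[in_band_harm >= config$soae_freq_range[1] &
                                 in_band_harm <= config$soae_freq_range[2]]
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n && tries < 1000L) {
    f <- stats::runif(1, config$soae_freq_range[1], config$soae_freq_range[2])
    ok <- abs(f - round(f / config$line_fundamental) *
                config$line_fundamental) > 10 &&
      (!length(in_band_harm) ||
         min(abs(f - in_band_harm)) > config$min_soae_separation) &&
      (!length(out) || min(abs(f - out)) >= config$min_soae_separation)
    if (ok) out <- c(out, f)
    tries <- tries + 1L
  }
  sort(out)
}

empty_oscillator_table <- function() {
  tibble::tibble(subject_id = character(), ear = character(),
                 frequency_hz = double(), level_db = double())
}

simulate_oscillators <- function(md, config) {
  rows <- purrr::map_dfr(seq_len(nrow(md)), function(i) {
    if (stats::runif(1) < config$prob_no_soae)
      return(tibble::tibble())
    lvl_mean <- if (md$group[i] == "mono") config$soae_level_mean_mono else
      config$soae_level_mean_bi
    purrr::map_dfr(c("left", "right"), function(ear) {
      n <- sample(0:4, 1, prob = config$soae_count_probs)
      if (n == 0L) return(tibble::tibble())
      tibble::tibble(
        subject_id = md$subject_id[i], ear = ear,
        frequency_hz = draw_soae_frequencies(n, config),
        level_db = rnorm(n, lvl_mean, config$soae_level_sd)
      )
    })
  })
  dplyr::bind_rows(empty_oscillator_table(), rows)
}

true_test_ear <- function(oscillators, subject_ids, range = c(1000, 10000)) {
  vapply(subject_ids, function(s) {
    o <- oscillators[oscillators$subject_id == s, , drop = FALSE]
    counts <- vapply(c("left", "right"), function(e)
      sum(o$ear == e & o$frequency_hz >= range[1] &
            o$frequency_hz <= range[2]), integer(1))
    if (sum(counts) == 0L) NA_character_
    else if (counts[["left"]] > counts[["right"]]) "left" else "right"
  }, character(1))
}

simulate_suppression_truth <- function(md, config) {
  is_bi <- md$group != "mono"
  pred <- -config$mu_suppression +
    config$b_control * md$control +
    config$b_wm * md$working_memory +
    config$b_interaction * md$control * md$working_memory +
    config$b_group * is_bi +
    config$b_aoa * md$english_aoa * is_bi
  eps <- rnorm(nrow(md), 0, config$residual_sd)
  magnitude <- pmax(0, -(pred + eps))
  tibble::tibble(subject_id = md$subject_id,
                 linear_predictor_db = pred, epsilon_db = eps,
                 magnitude_db = magnitude, expected_delta_db = -magnitude)
}

simulate_events <- function(md, config) {
  period <- trial_period_s(config)
  syllables <- c("ba", "da", "ga", "pa", "ta", "ka")
  purrr::map_dfr(md$subject_id, function(s) {
    syl <- sample(syllables, config$n_trials, replace = TRUE)
    correct <- stats::runif(config$n_trials) < 0.67
    resp <- ifelse(correct, syl,
                   vapply(syl, function(x)
                     sample(setdiff(syllables, x), 1), character(1)))
    onset <- config$task_start_s + (seq_len(config$n_trials) - 1) * period
    tibble::tibble(
      subject_id = s,
      trial_index = seq_len(config$n_trials),
      block = rep(seq_len(config$n_blocks),
                  each = config$n_trials / config$n_blocks),
      trial_onset_s = onset,
      speech_onset_s = onset + config$trial_lead_s,
      syllable = syl, response = resp
    )
  })
}

#' Simulate a cohort with known ground truth
#'
#' Generates subject metadata (language group, covariates, five task scores
#' and their composites), per-ear emission oscillators, per-subject injected
#' suppression magnitudes, and the trial-event table — optionally with full
#' ear-canal audio (baseline recordings for both ears plus a task recording
#' from the test ear). Everything is reproducible from `config$seed`, and
#' the returned ground truth is sufficient to recompute every injected
#' quantity.
#'
#' @param config A [cohort_config()].
#' @param audio If `TRUE`, synthesize waveforms for every subject (memory-
#'   and time-intensive for full-size cohorts); if `FALSE`, only tables.
#' @return An object of class `soae_cohort`: list with `metadata`, `events`,
#'   `truth` (list of `subjects`, `oscillators`), `waves` (per-subject list
#'   of `baseline_left`, `baseline_right`, `task`, or `NULL`), and `config`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_mono = 2, n_early = 2, n_late = 2,
#'                                      n_trials = 10, n_blocks = 2))
#' coh$truth$subjects
simulate_cohort <- function(config = cohort_config(), audio = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  tabs <- with_rng_seed(config$seed, {
    md <- simulate_subject_table(config)
    osc <- simulate_oscillators(md, config)
    md$has_soae <- md$subject_id %in% osc$subject_id
    md$test_ear <- true_test_ear(osc, md$subject_id)
    truth_subj <- simulate_suppression_truth(md, config)
    events <- simulate_events(md, config)
    list(md = md, osc = osc, truth_subj = truth_subj, events = events)
  })
  waves <- NULL
  if (audio) {
    waves <- lapply(seq_len(nrow(tabs$md)), function(i)
      simulate_subject_audio(tabs$md[i, ], tabs$osc, tabs$truth_subj,
                             tabs$events, config,
                             seed = config$seed + 13L * i))
    names(waves) <- tabs$md$subject_id
  }
  structure(list(metadata = tabs$md, events = tabs$events,
                 truth = list(subjects = tabs$truth_subj,
                              oscillators = tabs$osc),
                 waves = waves, config = config),
            class = "soae_cohort")
}

#' @export
print.soae_cohort <- function(x, ...) {
  cat(sprintf("<soae_cohort> %d subjects, %d trials each, audio: %s\n",
              nrow(x$metadata), x$config$n_trials,
              if (is.null(x$waves)) "no" else "yes"))
  invisible(x)
}

# Sum of a subject's oscillators for one ear over a given duration.
render_oscillators <- function(osc_rows, duration, config, seed) {
  n <- round(duration * config$sample_rate)
  x <- numeric(n)
  if (nrow(osc_rows)) {
    for (j in seq_len(nrow(osc_rows))) {
      spec <- oscillator_spec(osc_rows$frequency_hz[j],
                              osc_rows$level_db[j],
                              config$freq_jitter_sd, config$amp_jitter_sd)
      x <- x + simulate_soae_waveform(spec, duration, config$sample_rate,
                                      config$calibration_db,
                                      seed = seed + j)$samples
    }
  }
  x
}

add_background <- function(x, duration, config, seed) {
  x <- x + simulate_noise_floor(config$noise_floor_db, duration,
                                config$sample_rate, config$calibration_db,
                                seed = seed)$samples
  if (length(config$line_harmonics))
    x <- x + simulate_line_noise(config$line_fundamental,
                                 config$line_harmonics, config$line_levels,
                                 duration, config$sample_rate,
                                 config$calibration_db, seed = seed + 1L)$samples
  x
}

simulate_subject_audio <- function(md_row, oscillators, truth_subj, events,
                                   config, seed) {
  osc <- oscillators[oscillators$subject_id == md_row$subject_id, ,
                     drop = FALSE]
  out <- list()
  for (k in seq_along(c("left", "right"))) {
    ear <- c("left", "right")[k]
    x <- render_oscillators(osc[osc$ear == ear, , drop = FALSE],
                            config$baseline_duration_s, config,
                            seed = seed + 100L * k)
    x <- add_background(x, config$baseline_duration_s, config,
                        seed = seed + 100L * k + 50L)
    out[[paste0("baseline_", ear)]] <-
      ear_recording(x, config$sample_rate, config$calibration_db, ear)
  }
  ear <- md_row$test_ear
  if (!is.na(ear)) {
    dur <- task_duration_s(config)
    ev <- events[events$subject_id == md_row$subject_id, , drop = FALSE]
    mag <- truth_subj$magnitude_db[truth_subj$subject_id ==
                                     md_row$subject_id]
    x <- render_oscillators(osc[osc$ear == ear, , drop = FALSE], dur,
                            config, seed = seed + 300L)
    g <- suppression_envelope(
      suppression_spec(mag, config$suppression_onset_latency,
                       config$suppression_time_constant),
      ev, dur, config$sample_rate, config$speech_duration_s)
    x <- x * 10^(g / 20)
    x <- add_background(x, dur, config, seed = seed + 350L)
    out$task <- ear_recording(x, config$sample_rate, config$calibration_db,
                              ear)
  }
  out
}

#' Fast measurement-level simulation
#'
#' Draws trial-level suppression measurements directly from the cohort's
#' generative model, bypassing audio synthesis and spectral analysis: for
#' each (trial x test-ear emission), `delta_db = expected_delta +
#' N(0, trial_sd)`. This is the path used for large statistical calibration
#' simulations; the audio path validates that the spectral pipeline recovers
#' the same quantities.
#'
#' @param cohort A `soae_cohort` from [simulate_cohort()].
#' @param seed Seed for the trial-level noise (default derived from the
#'   cohort seed).
#' @return A measurement tibble in the same format as [measure_trials()],
#'   for subjects with a test ear.
#' @export
simulate_trial_measurements <- function(cohort, seed = NULL) {
  stopifnot(inherits(cohort, "soae_cohort"))
  config <- cohort$config
  if (is.null(seed)) seed <- config$seed + 7777L
  md <- cohort$metadata[!is.na(cohort$metadata$test_ear), , drop = FALSE]
  osc <- cohort$truth$oscillators
  with_rng_seed(seed, purrr::map_dfr(seq_len(nrow(md)), function(i) {
    s <- md$subject_id[i]
    o <- osc[osc$subject_id == s & osc$ear == md$test_ear[i], , drop = FALSE]
    if (!nrow(o)) return(tibble::tibble())
    tr <- cohort$truth$subjects[cohort$truth$subjects$subject_id == s, ]
    grid <- tidyr::expand_grid(trial_index = seq_len(config$n_trials),
                               soae_frequency_hz = o$frequency_hz)
    grid <- dplyr::left_join(
      grid, tibble::tibble(soae_frequency_hz = o$frequency_hz,
                           soae_level_db = o$level_db),
      by = "soae_frequency_hz")
    base <- grid$soae_level_db + rnorm(nrow(grid), 0, 0.2)
    delta <- tr$expected_delta_db + rnorm(nrow(grid), 0, config$trial_sd)
    tibble::tibble(
      subject_id = s, trial_index = grid$trial_index,
      soae_frequency_hz = grid$soae_frequency_hz,
      baseline_level_db = base, stimulus_level_db = base + delta,
      delta_db = delta,
      n_frames_baseline = 5L, n_frames_stimulus = 5L,
      missing_reason = NA_character_
    )
  }))
}
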