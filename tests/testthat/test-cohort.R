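# Cohort generation, ground truth, and dataset round trips.

test_that("default configuration mirrors the study design", {
  cfg <- cohort_config()
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$metadata), 32L)
  expect_equal(sum(coh$metadata$group == "mono"), 11L)
  expect_equal(sum(coh$metadata$group == "early_bi"), 11L)
  expect_equal(sum(coh$metadata$group == "late_bi"), 10L)
  ev1 <- coh$events[coh$events$subject_id == coh$metadata$subject_id[1], ]
  expect_equal(nrow(ev1), 240L)
  expect_equal(as.integer(table(ev1$block)), rep(24L, 10))
  expect_equal(ev1$speech_onset_s - ev1$trial_onset_s, rep(1.5, 240))
})

test_that("trial counts must divide into blocks", {
  expect_error(cohort_config(n_trials = 241), "divisible")
})

test_that("null effects and zero residual give magnitude mu exactly", {
  cfg <- reduced_config(seed = 3, b_control = 0, b_wm = 0,
                        b_interaction = 0, b_group = 0, residual_sd = 0)
  coh <- simulate_cohort(cfg)
  expect_equal(coh$truth$subjects$magnitude_db, rep(1, 12))
})

test_that("generation is deterministic from the seed", {
  cfg <- reduced_config(seed = 11, n_trials = 10)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  cfg_small <- cohort_config(n_mono = 1, n_early = 1, n_late = 0,
                             n_trials = 2, n_blocks = 1,
                             baseline_duration_s = 2, seed = 12)
  wa <- simulate_cohort(cfg_small, audio = TRUE)
  wb <- simulate_cohort(cfg_small, audio = TRUE)
  expect_identical(wa$waves, wb$waves)
})

test_that("injected suppression follows the generative model exactly", {
  cfg <- reduced_config(seed = 13)
  coh <- simulate_cohort(cfg)
  md <- coh$metadata
  tr <- coh$truth$subjects
  pred <- -cfg$mu_suppression + cfg$b_control * md$control +
    cfg$b_wm * md$working_memory +
    cfg$b_interaction * md$control * md$working_memory +
    cfg$b_group * (md$group != "mono")
  expect_equal(tr$linear_predictor_db, pred)
  expect_equal(tr$magnitude_db, pmax(0, -(pred + tr$epsilon_db)))
  expect_equal(tr$expected_delta_db, -tr$magnitude_db)
})

test_that("fast measurement path reflects the injected deltas", {
  cfg <- reduced_config(seed = 14)
  coh <- simulate_cohort(cfg)
  m <- simulate_trial_measurements(coh)
  per_subj <- tapply(m$delta_db, m$subject_id, mean)
  tr <- coh$truth$subjects
  inj <- setNames(tr$expected_delta_db, tr$subject_id)[names(per_subj)]
  expect_equal(as.numeric(per_subj), unname(inj), tolerance = 0.15)
  expect_true(mean(m$delta_db) < 0)
})

test_that("dataset round trip: manifest, tables, audio, ground truth", {
  cfg <- cohort_config(n_mono = 1, n_early = 1, n_late = 0, n_trials = 2,
                       n_blocks = 1, baseline_duration_s = 2, seed = 15)
  d1 <- withr::local_tempdir()
  coh <- generate_cohort(cfg, d1, audio = TRUE)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # refuse to overwrite without force
  expect_error(generate_cohort(cfg, d1), "force")
  # identical config -> identical manifest checksums
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, d2, audio = TRUE)
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"),
                            simplifyVector = TRUE)
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"),
                            simplifyVector = TRUE)
  expect_identical(m1$md5, m2$md5)
  # round trip restores tables, truth, and samples
  back <- read_cohort(d1)
  expect_equal(back$events, coh$events)
  expect_equal(as.data.frame(back$truth$subjects),
               as.data.frame(coh$truth$subjects))
  s1 <- coh$metadata$subject_id[1]
  expect_equal(back$waves[[s1]]$baseline_left$samples,
               coh$waves[[s1]]$baseline_left$samples, tolerance = 1e-7)
  expect_equal(back$config$seed, cfg$seed)
})

test_that("generate_cohort requires an output directory", {
  expect_error(generate_cohort(cohort_config()), "usage")
})

test_that("table readers enforce required columns and report bad rows", {
  ev <- make_events(3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, p)
  expect_equal(as.data.frame(read_events(p)), as.data.frame(ev))
  # empty table with header parses cleanly
  write_events(ev[0, ], p)
  expect_equal(nrow(read_events(p)), 0L)
  # missing required column is named
  bad <- ev; bad$syllable <- NULL
  expect_error(write_events(bad, p), "syllable")
  readr::write_tsv(bad, p)
  expect_error(read_events(p), "syllable")
})
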