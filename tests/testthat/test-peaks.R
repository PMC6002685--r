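# Exclusion filters, test-ear selection, and peak tracking.

test_that("stability filter applies the strict 6 dB rule to segment levels", {
  pk <- make_peaks(c(2000, 3000, 4000))
  segs <- rbind(c(-5, -5, -5, -5),   # SD 0 -> kept
                c(0, 12, 0, 12),     # SD = sqrt(48) ~ 6.93 -> removed
                c(0, 0, 0, 12))      # SD exactly 6 -> kept (strict >)
  out <- stability_filter(pk, segment_levels = segs)
  expect_equal(out$stability_sd_db, c(0, sqrt(48), 6))
  expect_equal(out$excluded_by, c("none", "stability", "none"))
})

test_that("stability filter measures segment levels from a real baseline", {
  # amplitude-modulated oscillator: ~0 dB SPL in segments 1 and 3,
  # ~12 dB in segments 2 and 4 -> SD ~ 6.93, excluded
  fs <- 44100
  seg <- function(level, seed)
    simulate_soae_waveform(oscillator_spec(2000, level), 30,
                           seed = seed)$samples
  x <- c(seg(0, 1), seg(12, 1), seg(0, 1), seg(12, 1))
  rec <- ear_recording(x, fs)
  steady <- simulate_soae_waveform(oscillator_spec(3000, -5), 120, seed = 2)
  rec$samples <- rec$samples + steady$samples
  out <- stability_filter(make_peaks(c(2000, 3000)), rec)
  expect_equal(out$stability_sd_db[1], sqrt(48), tolerance = 0.15)
  expect_equal(out$excluded_by, c("stability", "none"))
  expect_lt(out$stability_sd_db[2], 0.5)
})

test_that("stability filter refuses baselines shorter than 120 s", {
  rec <- ear_recording(numeric(44100 * 60), 44100)
  expect_error(stability_filter(make_peaks(2000), rec), "120")
})

test_that("line-noise filter excludes within 5 Hz of 60 Hz multiples, inclusive", {
  pk <- make_peaks(c(1080, 1068, 2995, 2000))
  out <- line_noise_filter(pk)
  expect_equal(out$excluded_by,
               c("line_noise", "none", "line_noise", "none"))
})

test_that("filters only set flags and commute", {
  pk <- make_peaks(c(1080, 2000, 3000))
  segs <- rbind(c(0, 12, 0, 12), c(-5, -5, -5, -5), c(0, 12, 0, 12))
  a <- line_noise_filter(stability_filter(pk, segment_levels = segs))
  b <- stability_filter(line_noise_filter(pk), segment_levels = segs)
  expect_identical(a, b)
  expect_identical(a$frequency_hz, pk$frequency_hz)
  expect_identical(a$baseline_level_db, pk$baseline_level_db)
})

test_that("test-ear selection counts surviving in-range peaks, ties right", {
  p3 <- make_peaks(c(1500, 2500, 3500))
  p1 <- make_peaks(2000)
  expect_equal(as.character(select_test_ear(p3, p1)), "left")
  # out-of-range peaks do not count
  p_out <- make_peaks(c(900, 10500))
  expect_equal(as.character(select_test_ear(p3, p_out)), "left")
  expect_equal(attr(select_test_ear(p3, p_out), "counts")[["right"]], 0L)
  # excluded peaks do not count
  p_ex <- make_peaks(c(1500, 2500, 3500, 4500))
  p_ex$excluded_by <- c("none", "stability", "line_noise", "none")
  expect_equal(attr(select_test_ear(p_ex, p1), "counts")[["left"]], 2L)
  # tie goes to the right ear
  expect_equal(as.character(select_test_ear(p3, make_peaks(c(2000, 3000, 4000)))),
               "right")
  expect_error(select_test_ear(make_peaks(numeric(0)), make_peaks(numeric(0))),
               "no surviving SOAEs")
})

test_that("peak tracking finds the highest in-window local maximum", {
  f <- seq(1900, 2100, by = 1)
  lv <- -30 + 10 * exp(-((f - 2010) / 5)^2)   # single bump at 2010
  sp <- tibble::tibble(frequency_hz = f, level_db = lv)
  out <- track_peak(sp, 2000)
  expect_equal(out$frequency_hz, 2010)
  # strictly monotonic window -> missing
  mono <- tibble::tibble(frequency_hz = f, level_db = (f - 1900) * 0.1)
  expect_true(is.na(track_peak(mono, 2000)$frequency_hz))
  # window boundary is inclusive: local max exactly at +25 Hz counts
  edge <- tibble::tibble(
    frequency_hz = f,
    level_db = -30 + 10 * exp(-((f - 2025) / 3)^2))
  expect_equal(track_peak(edge, 2000)$frequency_hz, 2025)
  # ... and one at +26 Hz does not
  past <- tibble::tibble(
    frequency_hz = f,
    level_db = -30 + 10 * exp(-((f - 2026) / 3)^2))
  expect_true(is.na(track_peak(past, 2000)$frequency_hz))
})
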