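#' Write a synthetic cohort to disk
#'
#' Materialises a cohort as a dataset directory: one WAV per subject-ear for
#' the baseline phase, one task WAV for the test ear, the trial-event and
#' subject-metadata tables, a ground-truth JSON sidecar (including the full
#' generating configuration, sufficient to recompute every injected
#' quantity), and a manifest listing every written file with its MD5
#' checksum. Identical configurations produce identical manifests.
#'
#' @param config A [cohort_config()], or an already-simulated `soae_cohort`.
#' @param dir Output directory (created if needed).
#' @param audio Write waveform audio (if `FALSE`, tables and ground truth
#'   only).
#' @param wav_format `"float32"` (lossless for this pipeline) or `"pcm16"`.
#' @param force Overwrite into a non-empty directory.
#' @return The simulated `soae_cohort`, invisibly, with attribute `dir`.
#' @export
generate_cohort <- function(config = cohort_config(), dir, audio = TRUE,
                            wav_format = "float32", force = FALSE) {
  if (missing(dir) || !nzchar(dir))
    stop("an output directory is required\nusage: generate_cohort(config, dir, ...)")
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory not empty (use force = TRUE to overwrite): ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (inherits(config, "soae_cohort")) config else
    simulate_cohort(config, audio = audio)
  cfg <- cohort$config

  files <- character(0)
  wr <- function(fun, x, name) {
    p <- file.path(dir, name)
    fun(x, p)
    files <<- c(files, name)
    p
  }
  wr(write_events, cohort$events, "events.tsv")
  wr(write_metadata, cohort$metadata, "metadata.tsv")
  gt <- list(config = unclass(cfg),
             subjects = cohort$truth$subjects,
             oscillators = cohort$truth$oscillators,
             test_ears = stats::setNames(as.list(cohort$metadata$test_ear),
                                         cohort$metadata$subject_id))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  files <- c(files, "ground_truth.json")

  if (audio && !is.null(cohort$waves)) {
    for (s in names(cohort$waves)) {
      w <- cohort$waves[[s]]
      for (phase in names(w)) {
        name <- sprintf("%s_%s.wav", s, phase)
        tryCatch(write_wav(w[[phase]], file.path(dir, name),
                           format = wav_format),
                 error = function(e)
                   stop("failed writing ", file.path(dir, name), ": ",
                        conditionMessage(e)))
        files <- c(files, name)
      }
    }
  }

  manifest <- tibble::tibble(
    file = sort(files),
    md5 = unname(tools::md5sum(file.path(dir, sort(files))))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(cohort, "dir") <- dir
  invisible(cohort)
}

#' Read a cohort dataset from disk
#'
#' Loads a dataset written by [generate_cohort()] back into a `soae_cohort`.
#' Every file listed in the manifest must be present; WAVs are read with the
#' calibration constant recorded in the ground-truth sidecar.
#'
#' @param dir Dataset directory.
#' @param audio Load the waveforms (set `FALSE` for tables only).
#' @return A `soae_cohort`.
#' @export
read_cohort <- function(dir, audio = TRUE) {
  gt_path <- file.path(dir, "ground_truth.json")
  if (!file.exists(gt_path)) stop("not a cohort dataset (no ground_truth.json): ", dir)
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  config <- do.call(cohort_config, gt$config[names(gt$config) %in%
                                               names(formals(cohort_config))])
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  missing_files <- manifest$file[!file.exists(file.path(dir, manifest$file))]
  if (length(missing_files))
    stop("dataset at ", dir, " is missing file(s) from its manifest: ",
         paste(missing_files, collapse = ", "))

  metadata <- read_metadata(file.path(dir, "metadata.tsv"))
  events <- read_events(file.path(dir, "events.tsv"))
  waves <- NULL
  if (audio) {
    waves <- lapply(metadata$subject_id, function(s) {
      out <- list()
      for (phase in c("baseline_left", "baseline_right", "task")) {
        p <- file.path(dir, sprintf("%s_%s.wav", s, phase))
        if (file.exists(p)) {
          ear <- if (phase == "task") {
            gt$test_ears[[s]]
          } else sub("baseline_", "", phase)
          out[[phase]] <- read_wav(p, calibration_db = config$calibration_db,
                                   ear = ear)
        }
      }
      out
    })
    names(waves) <- metadata$subject_id
  }
  structure(list(metadata = metadata, events = events,
                 truth = list(subjects = tibble::as_tibble(gt$subjects),
                              oscillators = tibble::as_tibble(gt$oscillators)),
                 waves = waves, config = config),
            class = "soae_cohort")
}
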