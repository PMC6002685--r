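# Delimited-table round trips for the pipeline's four table types. All
# tables are tab-separated with a header; readers validate required columns
# and report malformed rows with line numbers via readr's problem report.

required_columns <- list(
  events = c("subject_id", "trial_index", "block", "trial_onset_s",
             "speech_onset_s", "syllable", "response"),
  metadata = c("subject_id", "group", "english_aoa", "english_prof",
               "korean_prof", "vocabulary", "flanker", "working_memory",
               "card_sort", "pattern"),
  peaks = c("subject_id", "ear", "frequency_hz", "baseline_level_db",
            "stability_sd_db", "excluded_by"),
  measurements = c("subject_id", "trial_index", "soae_frequency_hz",
                   "baseline_level_db", "stimulus_level_db", "delta_db",
                   "n_frames_baseline", "n_frames_stimulus",
                   "missing_reason")
)

read_table_checked <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tb)
  if (nrow(probs))
    stop("malformed ", kind, " table ", path, ": row ", probs$row[1],
         ", ", probs$expected[1], " expected but got ", probs$actual[1])
  req <- required_columns[[kind]]
  missing_cols <- setdiff(req, names(tb))
  if (length(missing_cols))
    stop(kind, " table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  tb
}

write_table_checked <- function(x, path, kind) {
  req <- required_columns[[kind]]
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols))
    stop("cannot write ", kind, " table; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read or write the pipeline's tables
#'
#' Tab-separated round trips for the four table types the pipeline
#' exchanges: trial events, subject metadata, emission peaks, and
#' suppression measurements. Readers validate that all required columns are
#' present (naming any that are missing) and surface malformed rows with
#' their line numbers; an empty table with a valid header parses to an
#' empty tibble without error.
#'
#' @param path File path.
#' @param x Table to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name pipeline_tables
NULL

#' @rdname pipeline_tables
#' @export
read_events <- function(path) read_table_checked(path, "events")
#' @rdname pipeline_tables
#' @export
write_events <- function(x, path) write_table_checked(x, path, "events")
#' @rdname pipeline_tables
#' @export
read_metadata <- function(path) read_table_checked(path, "metadata")
#' @rdname pipeline_tables
#' @export
write_metadata <- function(x, path) write_table_checked(x, path, "metadata")
#' @rdname pipeline_tables
#' @export
read_peaks <- function(path) read_table_checked(path, "peaks")
#' @rdname pipeline_tables
#' @export
write_peaks <- function(x, path) write_table_checked(x, path, "peaks")
#' @rdname pipeline_tables
#' @export
read_measurements <- function(path) read_table_checked(path, "measurements")
#' @rdname pipeline_tables
#' @export
write_measurements <- function(x, path)
  write_table_checked(x, path, "measurements")
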