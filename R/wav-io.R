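#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the two encodings the package writes:
#' 16-bit integer PCM and 32-bit IEEE float, single channel. (No audio
#' package is assumed; the format is parsed directly with [readBin()].)
#'
#' @param path Path to a `.wav` file.
#' @param calibration_db Calibration constant to attach to the returned
#'   recording (dB SPL of a full-scale sinusoid); WAV carries no calibration,
#'   so it must be supplied (datasets written by [generate_cohort()] store it
#'   in their ground-truth sidecar).
#' @param ear Optional ear label.
#' @return An [ear_recording()].
#' @export
read_wav <- function(path, calibration_db = 30, ear = NA_character_) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz + sz %% 2L)
      fmt <- list(
        format   = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV (data before fmt): ", path)
      if (fmt$channels != 1L) stop("only mono WAV supported: ", path)
      if (fmt$format == 1L && fmt$bits == 16L) {
        n <- sz %/% 2L
        samples <- readBin(con, "integer", n, size = 2, signed = TRUE,
                           endian = "little") / 32767
      } else if (fmt$format == 3L && fmt$bits == 32L) {
        n <- sz %/% 4L
        samples <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bits): ", path)
      }
      break
    } else {
      seek(con, sz + sz %% 2L, origin = "current")
    }
  }
  if (is.null(samples)) stop("no data chunk found in WAV: ", path)
  ear_recording(samples, fmt$rate, calibration_db = calibration_db, ear = ear)
}

#' Write a mono WAV file
#'
#' @param recording An [ear_recording()].
#' @param path Output path.
#' @param format `"float32"` (IEEE float, lossless for this package's
#'   pipelines) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(recording, path, format = c("float32", "pcm16")) {
  stopifnot(inherits(recording, "ear_recording"))
  format <- match.arg(format)
  x <- recording$samples
  rate <- as.integer(round(recording$sample_rate))
  bytes_per <- if (format == "float32") 4L else 2L
  data_size <- length(x) * bytes_per

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeChar("RIFF", con, 4, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, 4, eos = NULL)
  writeChar("fmt ", con, 4, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt_code <- if (format == "float32") 3L else 1L
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * bytes_per, con, size = 4, endian = "little") # byte rate
  writeBin(bytes_per, con, size = 2, endian = "little")        # block align
  writeBin(8L * bytes_per, con, size = 2, endian = "little")
  writeChar("data", con, 4, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}
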