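#' Plot a baseline spectrum with detected emission peaks
#'
#' @param spectrum A `soae_spectrum` from [baseline_spectrum()].
#' @param peaks Optional peak table; surviving peaks are marked and excluded
#'   ones shown with their exclusion reason.
#' @param xlim Frequency range shown, Hz.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, peaks = NULL, xlim = c(500, 10000)) {
  p <- ggplot2::ggplot(spectrum,
                       ggplot2::aes(x = .data$frequency_hz,
                                    y = .data$level_db)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Level (dB SPL)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks)) {
    p <- p + ggplot2::geom_point(
      data = peaks,
      ggplot2::aes(x = .data$frequency_hz, y = .data$baseline_level_db,
                   colour = .data$excluded_by),
      size = 2) +
      ggplot2::labs(colour = "Excluded by")
  }
  p
}

#' Spectrogram heat map
#'
#' @param object A `soae_spectrogram`.
#' @param fmax Upper frequency bound shown, Hz.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.soae_spectrogram <- function(object, fmax = 8000, ...) {
  d <- as_tibble(object)
  d <- d[d$frequency_hz <= fmax, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$frequency_hz,
                                  fill = .data$level_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB SPL") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Mean suppression by language group
#'
#' Average per-trial change in emission level (dB) by language group, with
#' standard-error bars; more negative values indicate greater suppression
#' relative to the pre-trial baseline.
#'
#' @param measurements Measurement table (non-missing rows are used).
#' @param metadata Subject table with `subject_id` and `group`.
#' @return A ggplot object.
#' @export
plot_suppression_by_group <- function(measurements, metadata) {
  d <- measurements[is.na(measurements$missing_reason) |
                      !nzchar(measurements$missing_reason), , drop = FALSE]
  d <- dplyr::left_join(d, metadata[c("subject_id", "group")],
                        by = "subject_id")
  subj <- d |>
    dplyr::group_by(.data$group, .data$subject_id) |>
    dplyr::summarise(delta_db = mean(.data$delta_db, na.rm = TRUE),
                     .groups = "drop")
  summ <- subj |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_delta = mean(.data$delta_db),
                     se = stats::sd(.data$delta_db) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group,
                                     y = .data$mean_delta)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_delta - .data$se,
                                        ymax = .data$mean_delta + .data$se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Mean change in SOAE level (dB)") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted model
#'
#' @param object A `soae_fit`.
#' @param robust Use cluster-robust intervals when available.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.soae_fit <- function(object, robust = !is.null(object$vcov_cluster),
                              ...) {
  d <- tidy(object, robust = robust, conf.int = TRUE)
  d <- d[d$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Estimate (dB)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
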