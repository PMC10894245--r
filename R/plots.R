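#' Plot a cross-spectral density
#'
#' Auto-spectra of both nodes (log power) and the cross-spectral magnitude
#' and phase, against frequency.
#'
#' @param object A `spectral_data` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectral_data <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(frequency = object$freq, value = Re(object$csd[1, 1, ]),
                   panel = "power", series = "frontal"),
    tibble::tibble(frequency = object$freq, value = Re(object$csd[2, 2, ]),
                   panel = "power", series = "parietal"),
    tibble::tibble(frequency = object$freq, value = Mod(object$csd[1, 2, ]),
                   panel = "cross-magnitude", series = "frontal x parietal")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "spectral density",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an inversion result: fit against data and free-energy trace
#'
#' @param object An `inversion_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.inversion_result <- function(object, ...) {
  mk <- function(s, kind) dplyr::bind_rows(
    tibble::tibble(frequency = s$freq, value = Re(s$csd[1, 1, ]),
                   node = "frontal", kind = kind),
    tibble::tibble(frequency = s$freq, value = Re(s$csd[2, 2, ]),
                   node = "parietal", kind = kind)
  )
  df <- dplyr::bind_rows(mk(object$data, "data"), mk(object$fitted, "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency, y = .data$value,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~node) +
    ggplot2::labs(
      x = "frequency (Hz)", y = "power spectral density", colour = NULL,
      subtitle = sprintf("variance explained %.1f%%, F = %.1f",
                         object$variance_explained, object$free_energy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a group statistics report
#'
#' Adjusted p-values per parameter, grouped by family, with the 0.05
#' threshold marked.
#'
#' @param object A `stat_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stat_report <- function(object, ...) {
  df <- object$anova
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_fdr),
                                   y = .data$parameter,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(0.05), linetype = 2) +
    ggplot2::labs(x = expression(-log[10] ~ "FDR-adjusted p"), y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a time-domain simulation
#'
#' Observed virtual-electrode series for both nodes (subsampled for long
#' runs).
#'
#' @param object A `tcm_simulation`.
#' @param max_points At most this many samples per node are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tcm_simulation <- function(object, max_points = 5000, ...) {
  idx <- unique(round(seq(1, length(object$time),
                          length.out = min(max_points, length(object$time)))))
  df <- dplyr::bind_rows(
    tibble::tibble(time = object$time[idx] / 1000,
                   value = object$obs[idx, 1], node = "frontal"),
    tibble::tibble(time = object$time[idx] / 1000,
                   value = object$obs[idx, 2], node = "parietal")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~node, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "virtual electrode signal") +
    ggplot2::theme_minimal()
}

#' @export
plot.spectral_data <- function(x, ...) print(autoplot.spectral_data(x, ...))

#' @export
plot.inversion_result <- function(x, ...) print(autoplot.inversion_result(x, ...))

#' @export
plot.stat_report <- function(x, ...) print(autoplot.stat_report(x, ...))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
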