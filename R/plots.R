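# ggplot2 visualisations of the result objects

#' Plot an SV time series
#'
#' @param object An `sv_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sv_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$sv)) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "SV",
                  title = attr(object, "vessel_id")) +
    ggplot2::theme_minimal()
}

#' Plot a wavelet energy map (scalogram)
#'
#' Time-frequency energy on a log frequency axis; the hatched overlay marks
#' the cone of influence.
#'
#' @param object An `energy_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_map <- function(object, ...) {
  df <- tidy.energy_map(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$frequency_hz)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$energy)) +
    ggplot2::geom_point(
      data = df[df$in_coi & seq_len(nrow(df)) %% 7 == 0, ],
      shape = ".", alpha = 0.25
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "E(f, b)") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot an averaged wavelet spectrum
#'
#' @param object An `avg_spectrum`.
#' @param peak_band Optional band; if given, the most prominent in-band
#'   peak and its background level are marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.avg_spectrum <- function(object, peak_band = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$frequency_hz,
                                    y = .data$mean_energy)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "mean wavelet energy",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
  if (!is.null(peak_band)) {
    pk <- find_prominent_peak(object, peak_band)
    if (!is.null(pk)) {
      p <- p +
        ggplot2::geom_point(data = pk,
                            ggplot2::aes(x = .data$f_peak, y = .data$e_peak),
                            color = "red", size = 2) +
        ggplot2::geom_hline(yintercept = pk$e_background, linetype = 2,
                            color = "red")
    }
  }
  p
}

#' Overlay the protocol-period spectra of one vessel
#'
#' Mirrors the control / drug-1 / drug-2 spectrum comparison used to read
#' off drug responses.
#'
#' @param spectra Named list of `avg_spectrum` objects (e.g. from
#'   [protocol_spectra()]).
#' @param smooth Smooth at the transform resolution first (default TRUE).
#' @return A ggplot.
#' @export
plot_period_spectra <- function(spectra, smooth = TRUE) {
  df <- dplyr::bind_rows(purrr::imap(spectra, function(s, nm) {
    if (smooth) s <- smooth_spectrum(s)
    dplyr::mutate(as_tibble(s), period = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_hz,
                                   y = .data$mean_energy,
                                   color = .data$period)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "mean wavelet energy") +
    ggplot2::theme_minimal()
}

#' Plot an SV map
#'
#' @param object An `sv_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sv_map <- function(object, ...) {
  ny <- nrow(object$values)
  nx <- ncol(object$values)
  df <- tibble(
    x = rep(0:(nx - 1), each = ny),
    y = rep(0:(ny - 1), times = nx),
    sv = as.vector(object$values)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$sv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
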