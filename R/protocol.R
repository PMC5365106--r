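#' Experimental protocol timeline
#'
#' Describes the three-stage infusion protocol: a control period with saline
#' infusion, followed by two consecutive drug-infusion periods (a thromboxane
#' analogue, then a nitric-oxide donor in the motivating experiments).
#' Spectral averaging uses a fixed-length analysis window inside each period,
#' starting a fixed offset after the infusion begins; the defaults are a
#' 10-minute window starting 10 minutes into each period.
#'
#' @param control_duration,drug1_duration,drug2_duration Period lengths in
#'   seconds (defaults 35, 30 and 30 minutes).
#' @param analysis_window_offset Seconds between the start of a period and
#'   the start of its analysis window (default 10 min).
#' @param analysis_window_length Length of the analysis window in seconds
#'   (default 10 min).
#' @return A `protocol_timeline` list.
#' @examples
#' tl <- protocol_timeline()
#' analysis_windows(tl)
#' @export
protocol_timeline <- function(control_duration = 35 * 60,
                              drug1_duration = 30 * 60,
                              drug2_duration = 30 * 60,
                              analysis_window_offset = 10 * 60,
                              analysis_window_length = 10 * 60) {
  for (nm in c("control_duration", "drug1_duration", "drug2_duration",
               "analysis_window_offset", "analysis_window_length")) {
    stop_if_not_scalar(get(nm), nm, positive = nm != "analysis_window_offset")
  }
  if (analysis_window_offset < 0) abort("`analysis_window_offset` must be >= 0.")
  shortest <- min(control_duration, drug1_duration, drug2_duration)
  if (analysis_window_offset + analysis_window_length > shortest) {
    abort("analysis window (offset + length) must fit inside every protocol period.")
  }
  structure(
    list(
      control_duration = control_duration,
      drug1_duration = drug1_duration,
      drug2_duration = drug2_duration,
      analysis_window_offset = analysis_window_offset,
      analysis_window_length = analysis_window_length
    ),
    class = "protocol_timeline"
  )
}

timeline_total <- function(timeline) {
  timeline$control_duration + timeline$drug1_duration + timeline$drug2_duration
}

#' Period boundaries of a protocol timeline
#'
#' @param timeline A [protocol_timeline()].
#' @return Tibble with columns `period`, `start`, `end` (seconds).
#' @export
period_bounds <- function(timeline) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  starts <- cumsum(c(0, timeline$control_duration, timeline$drug1_duration))
  durs <- c(timeline$control_duration, timeline$drug1_duration,
            timeline$drug2_duration)
  tibble(period = c("control", "drug1", "drug2"),
         start = starts, end = starts + durs)
}

#' Spectral-averaging windows of a protocol timeline
#'
#' One window per period, `analysis_window_offset` seconds after the period
#' starts and `analysis_window_length` seconds long.
#'
#' @inheritParams period_bounds
#' @return Tibble with columns `period`, `start`, `end` (seconds).
#' @export
analysis_windows <- function(timeline) {
  bounds <- period_bounds(timeline)
  dplyr::mutate(bounds,
                start = .data$start + timeline$analysis_window_offset,
                end = .data$start + timeline$analysis_window_length)
}

#' @export
print.protocol_timeline <- function(x, ...) {
  cat(sprintf(
    "<protocol_timeline> control %g min | drug1 %g min | drug2 %g min (analysis window: %g-%g min into each period)\n",
    x$control_duration / 60, x$drug1_duration / 60, x$drug2_duration / 60,
    x$analysis_window_offset / 60,
    (x$analysis_window_offset + x$analysis_window_length) / 60
  ))
  invisible(x)
}
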