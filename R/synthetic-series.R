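#' Oscillatory component of a synthetic vessel signal
#'
#' Builds a one-row tibble describing a single multiplicative oscillation of a
#' synthetic speckle-variance (or pressure) signal: a sinusoid of given
#' frequency and relative amplitude, active between `onset` and `offset`,
#' optionally faded in/out with a 60 s linear ramp to avoid spectral splatter
#' from hard switching.
#'
#' Several components are combined by row-binding the tibbles; this is the
#' `components` argument understood by [generate_sv_series()],
#' [generate_pressure_signal()] and [generate_speckle_stack()].
#'
#' @param frequency Oscillation frequency in Hz (> 0).
#' @param rel_amplitude Relative amplitude as a fraction of the signal
#'   baseline, in `[0, 1)`.
#' @param phase Phase offset in radians.
#' @param onset,offset Activity window in seconds (`onset < offset`); use
#'   `offset = Inf` for "until the end of the recording".
#' @param envelope `"constant"` (rectangular window) or `"ramped"` (60 s
#'   linear ramps at onset and offset).
#' @return A one-row tibble with columns `frequency`, `rel_amplitude`,
#'   `phase`, `onset`, `offset`, `envelope`.
#' @examples
#' oscillatory_component(0.17, 0.2)
#' @export
oscillatory_component <- function(frequency, rel_amplitude, phase = 0,
                                  onset = 0, offset = Inf,
                                  envelope = c("constant", "ramped")) {
  envelope <- match.arg(envelope)
  stop_if_not_scalar(frequency, "frequency", positive = TRUE)
  if (!is_scalar_number(rel_amplitude) || rel_amplitude < 0 || rel_amplitude >= 1) {
    abort("`rel_amplitude` must be in [0, 1).")
  }
  stop_if_not_scalar(phase, "phase")
  if (!is.numeric(onset) || !is.numeric(offset) || onset >= offset) {
    abort("`onset` must be strictly less than `offset`.")
  }
  tibble(
    frequency = frequency, rel_amplitude = rel_amplitude, phase = phase,
    onset = onset, offset = offset, envelope = envelope
  )
}

ramp_seconds <- 60

# envelope of one component evaluated at times `t` (seconds)
component_envelope <- function(comp, t) {
  env <- as.numeric(t >= comp$onset & t < comp$offset)
  if (identical(comp$envelope, "ramped")) {
    span <- comp$offset - comp$onset
    ramp <- min(ramp_seconds, span / 2)
    if (ramp > 0) {
      up <- pmin(pmax((t - comp$onset) / ramp, 0), 1)
      down <- if (is.finite(comp$offset)) {
        pmin(pmax((comp$offset - t) / ramp, 0), 1)
      } else {
        1
      }
      env <- env * up * down
    }
  }
  env
}

validate_components <- function(components, fps) {
  if (is.null(components)) {
    return(tibble(
      frequency = numeric(), rel_amplitude = numeric(), phase = numeric(),
      onset = numeric(), offset = numeric(), envelope = character()
    ))
  }
  components <- as_tibble(components)
  needed <- c("frequency", "rel_amplitude", "phase", "onset", "offset", "envelope")
  missing <- setdiff(needed, names(components))
  if (length(missing) > 0) {
    abort(paste0("`components` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- components$frequency >= fps / 2
  if (any(bad)) {
    abort(sprintf(
      "Component frequency %g Hz is at or above the Nyquist limit (fps/2 = %g Hz); increase `fps` or drop the component.",
      components$frequency[which(bad)[1]], fps / 2
    ))
  }
  components
}

# sum of multiplicative modulations at times t: sum_i amp_i env_i sin(2 pi f t + phi)
modulation_at <- function(components, t) {
  mod <- numeric(length(t))
  for (i in seq_len(nrow(components))) {
    comp <- components[i, ]
    mod <- mod + comp$rel_amplitude * component_envelope(comp, t) *
      sin(2 * pi * comp$frequency * t + comp$phase)
  }
  mod
}

new_sv_series <- function(time, sv, fps, vessel_id = "v1") {
  out <- tibble(time = time, sv = sv)
  attr(out, "fps") <- fps
  attr(out, "vessel_id") <- vessel_id
  class(out) <- c("sv_series", class(out))
  out
}

#' Generate a synthetic per-vessel speckle-variance time series
#'
#' Emulates the 1-D SV(t) signal of a single retinal vessel: a positive
#' baseline, multiplicatively modulated by a set of oscillatory components
#' (vasomotion band, Mayer band, ventilation, cardiac), plus additive white
#' Gaussian measurement noise:
#' \deqn{sv(t) = \mathrm{baseline}\,\bigl(1 + \sum_i A_i\,\mathrm{env}_i(t)\,
#'   \sin(2\pi f_i t + \phi_i)\bigr) + \mathcal{N}(0, \sigma^2).}
#'
#' @param components Tibble of [oscillatory_component()] rows, or `NULL` for
#'   a noise-only signal.
#' @param baseline Baseline SV level (dimensionless, > 0).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param fps Sampling rate in Hz; must exceed twice every component
#'   frequency.
#' @param duration Recording length in seconds.
#' @param seed Integer seed for reproducibility (`NULL` = leave RNG alone).
#' @param vessel_id Identifier stored on the returned series.
#' @return An `sv_series`: a tibble with columns `time` (s) and `sv`, with
#'   attributes `fps` and `vessel_id`.
#' @examples
#' s <- generate_sv_series(oscillatory_component(0.17, 0.2),
#'                         baseline = 4, noise_sd = 0.1,
#'                         fps = 2, duration = 600, seed = 1)
#' head(s)
#' @export
generate_sv_series <- function(components = NULL, baseline = 4, noise_sd = 0,
                               fps = 2, duration, seed = NULL,
                               vessel_id = "v1") {
  stop_if_not_scalar(baseline, "baseline", positive = TRUE)
  stop_if_not_scalar(noise_sd, "noise_sd")
  stop_if_not_scalar(fps, "fps", positive = TRUE)
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  components <- validate_components(components, fps)
  n <- round(fps * duration)
  t <- (seq_len(n) - 1) / fps
  sv <- baseline * (1 + modulation_at(components, t))
  if (noise_sd > 0) {
    sv <- sv + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  new_sv_series(t, sv, fps, vessel_id)
}

#' Default systemic pressure components (pulse, ventilation, Mayer)
#'
#' The three rhythms visible in a rat arterial-pressure recording under
#' mechanical ventilation: the heart beat (default 6.4 Hz), lung ventilation
#' (1 Hz, i.e. 60 breaths/min) and Mayer waves (0.4-0.5 Hz in rats; default
#' 0.5 Hz).
#'
#' @param rel_amplitude Relative amplitude given to each component.
#' @param pulse,ventilation,mayer Component frequencies in Hz.
#' @return A three-row component tibble (see [oscillatory_component()]).
#' @export
systemic_components <- function(rel_amplitude = 0.2, pulse = 6.4,
                                ventilation = 1.0, mayer = 0.5) {
  dplyr::bind_rows(
    oscillatory_component(pulse, rel_amplitude),
    oscillatory_component(ventilation, rel_amplitude),
    oscillatory_component(mayer, rel_amplitude)
  )
}

# 1/f ("pink") noise with unit standard deviation, via spectral shaping of
# white Gaussian noise; deterministic under an active seed.
pink_noise <- function(n) {
  if (n < 2) return(rnorm(n))
  w <- rnorm(n)
  wf <- fft(w)
  k <- seq_len(n) - 1
  freq_idx <- pmin(k, n - k)          # symmetric frequency index
  scale <- ifelse(freq_idx == 0, 0, 1 / sqrt(freq_idx))
  x <- Re(fft(wf * scale, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate a synthetic arterial-pressure-like signal
#'
#' Produces a high-rate 1-D signal carrying the three systemic rhythms seen
#' in rat blood-pressure recordings (pulse, ventilation and Mayer waves) plus
#' optional 1/f ("pink") noise, for cross-validating the speckle pipeline
#' against an independent reference modality.
#'
#' @param duration Length in seconds (default 20 min). Ignored if `timeline`
#'   is supplied, in which case the full protocol length is used.
#' @param fps Sampling rate in Hz (>= 50 recommended so the cardiac line is
#'   well below Nyquist).
#' @param components Component tibble; defaults to [systemic_components()].
#' @param baseline Baseline pressure level (arbitrary units).
#' @param noise `"pink"`, `"white"` or `"none"`.
#' @param snr Signal-to-noise ratio: RMS of the oscillatory part divided by
#'   the noise standard deviation. Ignored when `noise = "none"`.
#' @param timeline Optional [protocol_timeline()]; sets `duration` to the
#'   total protocol length.
#' @param seed Integer seed.
#' @return An `sv_series` tibble (columns `time`, `sv`).
#' @export
generate_pressure_signal <- function(duration = 20 * 60, fps = 50,
                                     components = systemic_components(),
                                     baseline = 100,
                                     noise = c("pink", "white", "none"),
                                     snr = 10, timeline = NULL, seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(timeline)) {
    duration <- timeline_total(timeline)
  }
  stop_if_not_scalar(duration, "duration", positive = TRUE)
  stop_if_not_scalar(fps, "fps", positive = TRUE)
  components <- validate_components(components, fps)
  n <- round(fps * duration)
  t <- (seq_len(n) - 1) / fps
  sv <- baseline * (1 + modulation_at(components, t))
  if (noise != "none" && nrow(components) > 0 && is.finite(snr) && snr > 0) {
    rms <- baseline * sqrt(sum(components$rel_amplitude^2) / 2)
    noise_sd <- rms / snr
    sv <- sv + with_seed(seed, {
      if (noise == "pink") noise_sd * pink_noise(n) else rnorm(n, 0, noise_sd)
    })
  }
  new_sv_series(t, sv, fps, vessel_id = "pressure")
}

#' @export
print.sv_series <- function(x, ...) {
  cat(sprintf("<sv_series> vessel %s: %d samples at %g Hz (%.1f s)\n",
              attr(x, "vessel_id") %||% "?", nrow(x),
              attr(x, "fps"), nrow(x) / attr(x, "fps")))
  NextMethod()
}
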