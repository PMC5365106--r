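# Peak-prominence statistics: most-prominent-peak detection, noise
# background, energy ratio E, prominence ratio P, detection flags, and
# band-wise vessel classification.

#' Frequency bands of interest
#'
#' `vaso_bands()` returns the two default analysis bands: band 1
#' (0.1-0.3 Hz, retinal vasomotion) and band 2 (0.3-0.7 Hz, Mayer waves in
#' rats).  `band()` builds a single custom band.
#'
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @param label Band label.
#' @return A tibble with columns `label`, `f_lo`, `f_hi`.
#' @export
band <- function(f_lo, f_hi, label = sprintf("%g-%g Hz", f_lo, f_hi)) {
  stop_if_not_scalar(f_lo, "f_lo", positive = TRUE)
  stop_if_not_scalar(f_hi, "f_hi", positive = TRUE)
  if (f_hi <= f_lo) abort("`f_hi` must exceed `f_lo`.")
  tibble(label = label, f_lo = f_lo, f_hi = f_hi)
}

#' @rdname band
#' @export
vaso_bands <- function() {
  dplyr::bind_rows(band(0.1, 0.3, "band1"), band(0.3, 0.7, "band2"))
}

# systemic-rhythm bands used for pressure-vs-speckle cross-validation
#' @rdname band
#' @export
systemic_bands <- function() {
  dplyr::bind_rows(band(3, 9.6, "cardiac"),
                   band(0.7, 3, "ventilation"),
                   band(0.3, 0.7, "mayer"))
}

as_band <- function(b) {
  if (is.numeric(b) && length(b) == 2) b <- band(b[1], b[2])
  b <- as_tibble(b)
  stopifnot(all(c("f_lo", "f_hi") %in% names(b)), nrow(b) == 1)
  b
}

#' Noise-background estimate under a spectral peak
#'
#' The noise background at a peak is estimated as the median of the in-band
#' energies after excluding grid points within +/-20% (in frequency) of the
#' peak; when the exclusion empties the band, the whole-band median is used
#' with a warning.  Referencing the peak to the band-wide level (rather
#' than to a local baseline at the peak) deliberately raises the bar for
#' small local maxima riding low on a sloped noise floor: a detected peak
#' must stand out of the band as a whole.
#'
#' @param spectrum An `avg_spectrum`.
#' @param band A band (one-row tibble from [band()], or `c(f_lo, f_hi)`).
#' @param f_peak Peak frequency in Hz.
#' @return Background energy (positive scalar for any spectrum with
#'   positive in-band energy).
#' @export
estimate_background <- function(spectrum, band, f_peak) {
  band <- as_band(band)
  f <- spectrum$frequency_hz
  e <- spectrum$mean_energy
  in_band <- which(f >= band$f_lo & f <= band$f_hi & !is.na(e))
  if (length(in_band) == 0) abort("no usable in-band energies for the background.")
  keep <- in_band[abs(f[in_band] - f_peak) > 0.2 * f_peak]
  if (length(keep) == 0) {
    warn("peak exclusion empties the band; falling back to the whole-band median")
    keep <- in_band
  }
  median(e[keep])
}

#' Most prominent spectral peak in a band
#'
#' Identifies the strict local maxima of the spectrum whose frequency lies
#' strictly inside the band (band-edge maxima are not peaks, so a spectral
#' slope cannot masquerade as an oscillation), and returns the one with the
#' largest prominence, defined as peak energy minus the noise background
#' ([estimate_background()]).  Ties break toward the lower frequency.
#' Absence of any interior local maximum is a valid outcome (`NULL`).
#'
#' For a spectrum that has been smoothed ([smooth_spectrum()]), "interior"
#' is resolution-matched: maxima within one smoothing-kernel bandwidth of a
#' band edge cannot be located at the working resolution (smoothing and
#' slope can conspire to park a maximum just inside the boundary), so the
#' edge margin widens from one grid step to the kernel sd.  Raw spectra
#' keep the one-grid-step margin.
#'
#' @inheritParams estimate_background
#' @return A one-row tibble (`f_peak`, `e_peak`, `e_background`,
#'   `prominence`) or `NULL` when the band holds no peak.
#' @examples
#' sp <- tibble::tibble(
#'   frequency_hz = 0.05 * 2^(seq(0, 48) / 12),
#'   mean_energy = 1 + 3 * exp(-(log(0.05 * 2^(seq(0, 48) / 12) / 0.17))^2 / 0.005),
#'   n_points = 100L
#' )
#' class(sp) <- c("avg_spectrum", class(sp))
#' find_prominent_peak(sp, band(0.1, 0.3))
#' @export
find_prominent_peak <- function(spectrum, band) {
  band <- as_band(band)
  f <- spectrum$frequency_hz
  e <- spectrum$mean_energy
  in_band <- which(f >= band$f_lo & f <= band$f_hi)
  if (length(in_band) < 3) return(NULL)
  # edge margin: one grid step, widened to the smoothing bandwidth for
  # smoothed spectra (resolution-matched "interior")
  margin <- 1L
  bw <- attr(spectrum, "smoothed_bw")
  if (!is.null(bw) && bw > 0 && length(f) > 1) {
    step <- median(diff(log(f)))
    margin <- max(1L, ceiling(bw / step))
  }
  if (length(in_band) <= 2 * margin) return(NULL)
  interior <- in_band[-c(seq_len(margin),
                         length(in_band) + 1 - seq_len(margin))]
  best <- NULL
  for (k in interior) {
    if (k == 1 || k == length(e)) next
    if (is.na(e[k]) || is.na(e[k - 1]) || is.na(e[k + 1])) next
    if (e[k] > e[k - 1] && e[k] > e[k + 1]) {
      bg <- estimate_background(spectrum, band, f[k])
      prom <- e[k] - bg
      if (is.null(best) || prom > best$prominence) {
        best <- tibble(f_peak = f[k], e_peak = e[k], e_background = bg,
                       prominence = prom)
      }
    }
  }
  best
}

#' Energy ratio between response and control spectra
#'
#' \deqn{E = E_r(f_r) / E_c(f_r):} the energy of the response spectrum at
#' its own most prominent in-band peak frequency \eqn{f_r}, divided by the
#' *control* energy evaluated at that same frequency.  Values above 1
#' indicate increased oscillatory activity after drug infusion.
#'
#' @param response,control `avg_spectrum` objects on the same frequency
#'   grid.
#' @param band The analysis band.
#' @return A scalar, or `NA` when the response has no in-band peak (with a
#'   warning when the control energy at `f_r` is zero or missing).
#' @export
energy_ratio <- function(response, control, band) {
  check_same_grid(response, control)
  pk <- find_prominent_peak(response, band)
  if (is.null(pk)) return(NA_real_)
  ec <- control$mean_energy[match_freq(control, pk$f_peak)]
  if (is.na(ec) || ec <= 0) {
    warn("control energy at the response peak frequency is zero or missing; energy ratio undefined")
    return(NA_real_)
  }
  pk$e_peak / ec
}

#' Prominence ratio between response and control spectra
#'
#' \deqn{P = P_r / P_c = \frac{E_r(f_r) - E_{rb}}{E_c(f_c) - E_{cb}}:} the
#' prominence (peak height above the noise background) of the most prominent
#' in-band response peak, relative to that of the most prominent control
#' peak.  The two peaks may sit at different frequencies.  `P > 1.1` is the
#' working definition of at least 10% induced increase in activity.
#'
#' @details The response prominence requires a genuine (strict interior)
#'   in-band peak: without one there is nothing detected and `P` is `NA`.
#'   The control prominence is only the *reference level*: when the control
#'   spectrum is featureless in the band (no strict interior maximum, the
#'   typical case for a quiescent vessel), it falls back to the prominence
#'   of the in-band energy maximum above the noise background, so that
#'   drug-initiated activity in a previously silent vessel still yields a
#'   defined, large `P` - mirroring how the energy ratio evaluates the
#'   control spectrum at the response frequency without requiring a control
#'   peak.
#'
#' @inheritParams energy_ratio
#' @return A scalar, or `NA` when the response lacks an in-band peak or the
#'   control prominence is not positive (with a warning).
#' @export
prominence_ratio <- function(response, control, band) {
  check_same_grid(response, control)
  pr <- find_prominent_peak(response, band)
  if (is.null(pr)) return(NA_real_)
  pc <- find_prominent_peak(control, band) %||% band_max_prominence(control, band)
  if (is.null(pc) || !is.finite(pc$prominence) || pc$prominence <= 0) {
    warn("control peak prominence is not positive; prominence ratio undefined")
    return(NA_real_)
  }
  pr$prominence / pc$prominence
}

# reference prominence of a peakless spectrum: in-band maximum above the
# background estimated at that maximum
band_max_prominence <- function(spectrum, band) {
  band <- as_band(band)
  f <- spectrum$frequency_hz
  e <- spectrum$mean_energy
  in_band <- which(f >= band$f_lo & f <= band$f_hi & !is.na(e))
  if (length(in_band) == 0) return(NULL)
  k <- in_band[which.max(e[in_band])]
  bg <- estimate_background(spectrum, band, f[k])
  tibble(f_peak = f[k], e_peak = e[k], e_background = bg,
         prominence = e[k] - bg)
}

check_same_grid <- function(a, b) {
  if (length(a$frequency_hz) != length(b$frequency_hz) ||
      any(abs(a$frequency_hz - b$frequency_hz) >
            1e-9 * pmax(a$frequency_hz, 1))) {
    abort("spectra must share the same frequency grid.")
  }
  invisible(TRUE)
}

match_freq <- function(spectrum, f) {
  which.min(abs(spectrum$frequency_hz - f))
}

#' Classify a vessel's oscillatory activity per band and drug period
#'
#' Applies the full set of detection rules to one vessel's averaged spectra:
#'
#' * **spontaneous**: the control spectrum holds an in-band peak with
#'   `E_c(f_c) / E_cb > threshold` (peak energy at least 10% above the noise
#'   background, at the default threshold of 1.1);
#' * **increased** (the n-count rule): prominence ratio `P > threshold`;
#' * **above_background**: the response peak satisfies
#'   `E_r(f_r) / E_rb > threshold`;
#' * **induced**: above background in the response *and* not spontaneous in
#'   the control (activity initiated, not merely amplified, by the drug).
#'
#' Spectra are smoothed at the transform resolution ([smooth_spectrum()])
#' before peak analysis; pass `smooth_bw = 0` to disable.  Missing response
#' spectra yield `NA` flags (missing, not `FALSE`).
#'
#' @param spectra Named list of `avg_spectrum` objects: `control` plus any
#'   of `drug1`, `drug2`.
#' @param bands Tibble of bands (default [vaso_bands()]).
#' @param threshold Detection threshold (default 1.1 = 10% above).
#' @param smooth_bw Smoothing bandwidth forwarded to [smooth_spectrum()];
#'   `NULL` = the transform's intrinsic resolution.
#' @param vessel_id Identifier attached to the output rows.
#' @return A tibble with one row per band x response period: columns
#'   `vessel_id`, `band`, `period`, `f_control`, `spontaneous`,
#'   `f_response`, `energy_ratio`, `prominence_ratio`, `increased`,
#'   `above_background`, `induced`.
#' @export
classify_vessel <- function(spectra, bands = vaso_bands(), threshold = 1.1,
                            smooth_bw = NULL, vessel_id = "v1") {
  if (!is.list(spectra) || !"control" %in% names(spectra)) {
    abort("`spectra` must be a named list containing at least `control`.")
  }
  spectra <- purrr::map(spectra, function(s) {
    if (is.null(s)) NULL else smooth_spectrum(s, bw = smooth_bw)
  })
  control <- spectra$control
  periods <- intersect(c("drug1", "drug2"), names(spectra))
  if (length(periods) == 0) periods <- NA_character_

  rows <- purrr::map(seq_len(nrow(bands)), function(bi) {
    bnd <- bands[bi, ]
    pc <- find_prominent_peak(control, bnd)
    spont <- if (is.null(pc)) FALSE else unname(pc$e_peak / pc$e_background > threshold)
    purrr::map(periods, function(per) {
      if (is.na(per) || is.null(spectra[[per]])) {
        return(tibble(
          vessel_id = vessel_id, band = bnd$label, period = per,
          f_control = if (is.null(pc)) NA_real_ else pc$f_peak,
          spontaneous = spont,
          f_response = NA_real_, energy_ratio = NA_real_,
          prominence_ratio = NA_real_, increased = NA,
          above_background = NA, induced = NA
        ))
      }
      resp <- spectra[[per]]
      pr <- find_prominent_peak(resp, bnd)
      e_ratio <- energy_ratio(resp, control, bnd)
      p_ratio <- prominence_ratio(resp, control, bnd)
      above <- if (is.null(pr)) FALSE else unname(pr$e_peak / pr$e_background > threshold)
      tibble(
        vessel_id = vessel_id, band = bnd$label, period = per,
        f_control = if (is.null(pc)) NA_real_ else pc$f_peak,
        spontaneous = spont,
        f_response = if (is.null(pr)) NA_real_ else pr$f_peak,
        energy_ratio = e_ratio,
        prominence_ratio = p_ratio,
        increased = if (is.na(p_ratio)) NA else p_ratio > threshold,
        above_background = above,
        induced = above & !spont
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Cohort summary in the style of a per-animal detection table
#'
#' Aggregates per-vessel classification rows ([classify_vessel()]) into a
#' per-animal (plus Total) table, for each drug period: `N` vessels,
#' `m1`/`m2` spontaneous detections per band, `n1`/`n2` vessels with
#' increased activity (prominence ratio above threshold), and the mean +/-
#' SD (sample SD, n-1) of the energy ratio `E` and peak frequency `f`
#' computed over the increased (`n`-flagged) vessels of each band.
#'
#' @param metrics Tibble of classification rows, from [classify_vessel()]
#'   (optionally row-bound over vessels).
#' @param vessels Optional tibble with columns `vessel_id`, `animal`;
#'   without it all vessels fall in one animal.
#' @return A tibble with one row per (period, animal) plus a `"Total"` row
#'   per period; columns `period`, `animal`, `N`, `m1`, `E1_mean`, `E1_sd`,
#'   `f1_mean`, `f1_sd`, `n1`, `m2`, `E2_mean`, `E2_sd`, `f2_mean`,
#'   `f2_sd`, `n2`.
#' @export
summarize_cohort <- function(metrics, vessels = NULL) {
  stopifnot(is.data.frame(metrics), nrow(metrics) > 0)
  if (is.null(vessels)) {
    vessels <- tibble(vessel_id = unique(metrics$vessel_id), animal = "animal1")
  }
  metrics <- dplyr::left_join(metrics, vessels, by = "vessel_id")
  metrics$animal[is.na(metrics$animal)] <- "animal1"

  one_group <- function(df) {
    out <- list(N = dplyr::n_distinct(df$vessel_id))
    for (bi in 1:2) {
      b <- paste0("band", bi)
      rows <- df[df$band == b, ]
      per_vessel <- rows[!duplicated(rows$vessel_id), ]
      out[[paste0("m", bi)]] <- sum(per_vessel$spontaneous, na.rm = TRUE)
      inc <- rows[!is.na(rows$increased) & rows$increased, ]
      out[[paste0("E", bi, "_mean")]] <- if (nrow(inc)) mean(inc$energy_ratio, na.rm = TRUE) else NA_real_
      out[[paste0("E", bi, "_sd")]] <- if (nrow(inc) > 1) sd(inc$energy_ratio, na.rm = TRUE) else NA_real_
      out[[paste0("f", bi, "_mean")]] <- if (nrow(inc)) mean(inc$f_response, na.rm = TRUE) else NA_real_
      out[[paste0("f", bi, "_sd")]] <- if (nrow(inc) > 1) sd(inc$f_response, na.rm = TRUE) else NA_real_
      out[[paste0("n", bi)]] <- nrow(inc)
    }
    as_tibble(out)[, c("N", "m1", "E1_mean", "E1_sd", "f1_mean", "f1_sd", "n1",
                       "m2", "E2_mean", "E2_sd", "f2_mean", "f2_sd", "n2")]
  }

  periods <- unique(metrics$period)
  periods <- periods[!is.na(periods)]
  if (length(periods) == 0) periods <- NA_character_
  out <- purrr::map(periods, function(per) {
    sub <- if (is.na(per)) metrics else metrics[metrics$period == per | is.na(metrics$period), ]
    by_animal <- dplyr::group_by(sub, .data$animal)
    rows <- dplyr::group_modify(by_animal, function(df, key) one_group(df))
    rows <- dplyr::ungroup(rows)
    total <- dplyr::mutate(one_group(sub), animal = "Total", .before = 1)
    dplyr::mutate(dplyr::bind_rows(rows, total), period = per, .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Paired comparison of induced-vasomotion frequencies across drugs
#'
#' Paired two-sided t-test on per-vessel peak-frequency differences between
#' two drug administrations.  Vessels with a missing frequency in either
#' condition are dropped.  Degenerate inputs are reported rather than
#' errored: all-zero differences give `p = 1` with a note; fewer than two
#' complete pairs gives `NA` results with a note.
#'
#' @param freqs_drug1,freqs_drug2 Per-vessel peak frequencies (Hz), paired
#'   by position.
#' @return A one-row tibble: `n_pairs`, `mean_diff`, `statistic`, `df`,
#'   `p_value`, `note`.
#' @export
compare_frequencies <- function(freqs_drug1, freqs_drug2) {
  if (length(freqs_drug1) != length(freqs_drug2)) {
    abort("frequency vectors must be paired (equal length).")
  }
  ok <- !is.na(freqs_drug1) & !is.na(freqs_drug2)
  x <- freqs_drug1[ok]
  y <- freqs_drug2[ok]
  if (length(x) < 2) {
    return(tibble(n_pairs = length(x), mean_diff = NA_real_,
                  statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                  note = "fewer than 2 complete pairs; test undefined"))
  }
  d <- x - y
  if (all(d == 0)) {
    return(tibble(n_pairs = length(x), mean_diff = 0, statistic = NA_real_,
                  df = length(x) - 1, p_value = 1,
                  note = "all paired differences are zero"))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble(n_pairs = length(x), mean_diff = unname(tt$estimate),
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, note = NA_character_)
}
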