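# End-to-end orchestration: simulate -> spectra -> metrics -> report,
# with validated configuration and reproducible seeds.

run_config_defaults <- function() {
  list(
    simulation = list(
      n_vessels = 3, spontaneous_band1 = 0, spontaneous_band2 = 0,
      induced = NULL, fps = 2, baseline = 4, rel_amplitude = 0.2,
      noise_sd = NULL, animals = NULL
    ),
    timeline = list(
      control_duration = 35 * 60, drug1_duration = 30 * 60,
      drug2_duration = 30 * 60, analysis_window_offset = 10 * 60,
      analysis_window_length = 10 * 60
    ),
    wavelet = list(
      omega0 = 6, voices = 12, f_min = 0.05, f_max = NULL,
      normalization = "1/a", smooth_bw = NULL
    ),
    bands = list(band1 = c(0.1, 0.3), band2 = c(0.3, 0.7)),
    threshold = 1.1,
    seed = 1,
    output_dir = NULL,
    write_series = FALSE
  )
}

#' Build and validate a pipeline configuration
#'
#' Configuration is a nested list mirroring the pipeline stages: a
#' `simulation` block (arguments of [generate_cohort()]), a `timeline`
#' block ([protocol_timeline()] arguments), a `wavelet` block, `bands`,
#' the detection `threshold`, a `seed` and an optional `output_dir`.
#' Unknown keys anywhere are rejected before any stage runs.
#'
#' @param ... Named overrides of the defaults, nested lists allowed (e.g.
#'   `simulation = list(n_vessels = 10)` replaces just that field).
#' @return A validated `run_config` list.
#' @examples
#' cfg <- run_config(simulation = list(n_vessels = 2), seed = 7)
#' @export
run_config <- function(...) {
  overrides <- list(...)
  cfg <- run_config_defaults()
  check_keys <- function(given, allowed, where) {
    extra <- setdiff(names(given), allowed)
    if (length(extra) > 0) {
      abort(sprintf("Unknown config key(s) in %s: %s", where,
                    paste(extra, collapse = ", ")))
    }
  }
  check_keys(overrides, names(cfg), "run_config()")
  for (blk in c("simulation", "timeline", "wavelet")) {
    if (!is.null(overrides[[blk]])) {
      check_keys(overrides[[blk]], names(cfg[[blk]]), blk)
      cfg[[blk]] <- modifyList(cfg[[blk]], overrides[[blk]],
                               keep.null = TRUE)
      overrides[[blk]] <- NULL
    }
  }
  cfg <- modifyList(cfg, overrides, keep.null = TRUE)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  tl <- do.call(protocol_timeline, cfg$timeline)  # errors if inconsistent
  for (bn in names(cfg$bands)) {
    b <- cfg$bands[[bn]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] <= 0 || b[2] <= b[1]) {
      abort(sprintf("band `%s` must be c(f_lo, f_hi) with 0 < f_lo < f_hi.", bn))
    }
  }
  if (!is_scalar_number(cfg$threshold) || cfg$threshold <= 0) {
    abort("`threshold` must be a positive number.")
  }
  fps <- cfg$simulation$fps
  f_max <- cfg$wavelet$f_max %||% min(9.6, fps / 2.5)
  if (f_max >= fps / 2) abort("wavelet f_max must stay below Nyquist (fps/2).")
  structure(cfg, class = "run_config", timeline = tl)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [run_config()] fields.
#' @param ... Further overrides applied on top of the file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  do.call(run_config, modifyList(y %||% list(), list(...), keep.null = TRUE))
}

config_bands <- function(cfg) {
  dplyr::bind_rows(purrr::imap(cfg$bands, function(b, nm) band(b[1], b[2], nm)))
}

#' Averaged spectra of one SV series over the protocol windows
#'
#' Convenience wrapper chaining [cwt_morlet()], [wavelet_energy()] and
#' [average_spectrum()] for the three protocol analysis windows.
#'
#' @param series An `sv_series` covering the full protocol.
#' @param timeline A [protocol_timeline()].
#' @param grid,omega0,normalization Forwarded to [cwt_morlet()].
#' @return Named list of `avg_spectrum` objects (`control`, `drug1`,
#'   `drug2`).
#' @export
protocol_spectra <- function(series, timeline = protocol_timeline(),
                             grid = NULL, omega0 = 6,
                             normalization = "1/a") {
  E <- wavelet_energy(cwt_morlet(series, grid = grid, omega0 = omega0,
                                 normalization = normalization))
  wins <- analysis_windows(timeline)
  out <- purrr::map(seq_len(nrow(wins)), function(i) {
    average_spectrum(E, c(wins$start[i], wins$end[i]), label = wins$period[i])
  })
  setNames(out, wins$period)
}

#' Run the full vasomotion-detection pipeline
#'
#' Orchestrates an end-to-end run on synthetic data: cohort simulation with
#' ground truth, Morlet wavelet energy spectra averaged over the protocol
#' windows, per-vessel classification, and per-animal summary tables.  With
#' an `output_dir`, all result tables are written out (CSV/JSON) together
#' with a machine-readable run manifest (package version, full
#' configuration, seed), from which the run can be regenerated exactly;
#' identical configurations give identical results.
#'
#' @param config A [run_config()].
#' @return A `vaso_run` list: `config`, `manifest` (cohort ground truth),
#'   `spectra` (per vessel), `metrics` (tibble), `summary` (tibble),
#'   `comparison` (paired frequency test between the drug periods, per
#'   band).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  tl <- attr(config, "timeline")
  sim <- config$simulation
  cohort <- generate_cohort(
    n_vessels = sim$n_vessels,
    spontaneous_band1 = sim$spontaneous_band1,
    spontaneous_band2 = sim$spontaneous_band2,
    induced = sim$induced, timeline = tl, fps = sim$fps,
    baseline = sim$baseline, rel_amplitude = sim$rel_amplitude,
    noise_sd = sim$noise_sd, animals = sim$animals, seed = config$seed
  )
  grid <- frequency_grid(sim$fps, f_min = config$wavelet$f_min,
                         f_max = config$wavelet$f_max,
                         voices = config$wavelet$voices)
  bands <- config_bands(config)
  spectra <- purrr::map(cohort$series, protocol_spectra, timeline = tl,
                        grid = grid, omega0 = config$wavelet$omega0,
                        normalization = config$wavelet$normalization)
  metrics <- dplyr::bind_rows(purrr::imap(spectra, function(sp, vid) {
    classify_vessel(sp, bands = bands, threshold = config$threshold,
                    smooth_bw = config$wavelet$smooth_bw, vessel_id = vid)
  }))
  summary <- summarize_cohort(metrics, cohort$manifest$vessels)
  comparison <- dplyr::bind_rows(purrr::map(bands$label, function(b) {
    wide <- tidyr::pivot_wider(
      metrics[metrics$band == b, c("vessel_id", "period", "f_response")],
      names_from = "period", values_from = "f_response"
    )
    if (!all(c("drug1", "drug2") %in% names(wide))) return(NULL)
    dplyr::mutate(compare_frequencies(wide$drug1, wide$drug2),
                  band = b, .before = 1)
  }))
  run <- structure(
    list(config = config, manifest = cohort$manifest, series = cohort$series,
         spectra = spectra, metrics = metrics, summary = summary,
         comparison = comparison),
    class = "vaso_run"
  )
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  write.csv(run$metrics, file.path(dir, "vessel_metrics.csv"), row.names = FALSE)
  jsonlite::write_json(run$metrics, file.path(dir, "vessel_metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(run$summary, file.path(dir, "cohort_summary.csv"), row.names = FALSE)
  if (nrow(run$comparison %||% tibble()) > 0) {
    write.csv(run$comparison, file.path(dir, "frequency_comparison.csv"),
              row.names = FALSE)
  }
  spectra_long <- dplyr::bind_rows(purrr::imap(run$spectra, function(sp, vid) {
    dplyr::bind_rows(purrr::imap(sp, function(s, per) {
      dplyr::mutate(as_tibble(s), vessel_id = vid, window_label = per)
    }))
  }))
  write.csv(spectra_long, file.path(dir, "averaged_spectra.csv"),
            row.names = FALSE)
  if (isTRUE(cfg$write_series)) {
    series_long <- dplyr::bind_rows(purrr::imap(run$series, function(s, vid) {
      dplyr::mutate(as_tibble(s), vessel_id = vid)
    }))
    write.csv(series_long, file.path(dir, "sv_series.csv"), row.names = FALSE)
  }
  write_manifest(run$manifest, file.path(dir, "cohort_manifest.json"))
  jsonlite::write_json(
    list(package = "vasowave",
         version = as.character(utils::packageVersion("vasowave")),
         seed = cfg$seed,
         config = unclass(cfg)),
    file.path(dir, "run_manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}

#' @export
print.vaso_run <- function(x, ...) {
  cat(sprintf("<vaso_run> %d vessels | seed %s\n", length(x$series),
              format(x$config$seed)))
  print(x$summary)
  invisible(x)
}

#' Cross-validate a speckle spectrum against a reference spectrum
#'
#' Compares the prominent peaks of an SV-derived spectrum with those of an
#' independently recorded reference (e.g. arterial blood pressure) in named
#' systemic-rhythm bands (cardiac, ventilation, Mayer by default).  Peaks
#' agree when their frequencies differ by at most one grid step.  If the
#' two spectra share no frequency range, a zero-row report is returned with
#' attribute `overlap = FALSE` and a message.
#'
#' @param sv_spectrum,reference_spectrum `avg_spectrum` objects (grids may
#'   differ).
#' @param bands Tibble of bands (default [systemic_bands()]).
#' @param smooth Smooth both spectra at the transform resolution first
#'   (default TRUE).
#' @return Tibble with columns `band`, `f_speckle`, `f_reference`, `agree`;
#'   attribute `overlap`.
#' @export
validate_against_reference <- function(sv_spectrum, reference_spectrum,
                                       bands = systemic_bands(),
                                       smooth = TRUE) {
  lo <- max(min(sv_spectrum$frequency_hz), min(reference_spectrum$frequency_hz))
  hi <- min(max(sv_spectrum$frequency_hz), max(reference_spectrum$frequency_hz))
  if (hi <= lo) {
    inform("the two spectra share no frequency overlap; nothing to compare")
    out <- tibble(band = character(), f_speckle = numeric(),
                  f_reference = numeric(), agree = logical())
    attr(out, "overlap") <- FALSE
    return(out)
  }
  if (smooth) {
    sv_spectrum <- smooth_spectrum(sv_spectrum)
    reference_spectrum <- smooth_spectrum(reference_spectrum)
  }
  voices <- attr(sv_spectrum, "voices") %||% 12
  step <- 2^(1 / voices)
  rows <- purrr::map(seq_len(nrow(bands)), function(i) {
    bnd <- bands[i, ]
    b_lo <- max(bnd$f_lo, lo)
    b_hi <- min(bnd$f_hi, hi)
    if (b_hi <= b_lo) return(NULL)
    bnd_clip <- band(b_lo, b_hi, bnd$label)
    p_sv <- find_prominent_peak(sv_spectrum, bnd_clip)
    p_ref <- find_prominent_peak(reference_spectrum, bnd_clip)
    tibble(
      band = bnd$label,
      f_speckle = if (is.null(p_sv)) NA_real_ else p_sv$f_peak,
      f_reference = if (is.null(p_ref)) NA_real_ else p_ref$f_peak,
      agree = if (is.null(p_sv) || is.null(p_ref)) FALSE else {
        ratio <- max(p_sv$f_peak, p_ref$f_peak) / min(p_sv$f_peak, p_ref$f_peak)
        ratio <= step * (1 + 1e-9)
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "overlap") <- TRUE
  out
}
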