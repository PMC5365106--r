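#' Generate a synthetic cohort of vessel SV series with known ground truth
#'
#' Builds a cohort of per-vessel speckle-variance time series spanning the
#' full protocol (control, drug-1, drug-2), in which designated vessels carry
#' oscillatory components in the vasomotion band (band 1, 0.1-0.3 Hz) and/or
#' the Mayer band (band 2, 0.3-0.7 Hz):
#'
#' * *spontaneous* vessels oscillate throughout the whole recording, at a
#'   frequency drawn uniformly from `spontaneous_freq` for their band;
#' * *induced* vessels oscillate only during the designated drug period
#'   (60 s ramped onset/offset), at the fixed band frequency in
#'   `induced_freq`;
#' * all remaining vessels are noise-only.
#'
#' The returned manifest records the truth for every vessel, so downstream
#' detection statistics can be scored against it.
#'
#' @param n_vessels Total number of vessels.
#' @param spontaneous_band1,spontaneous_band2 Number of vessels with
#'   spontaneous band-1 / band-2 activity.
#' @param induced Named integer vector of induced-vasomotion counts with any
#'   of the names `band1_drug1`, `band2_drug1`, `band1_drug2`, `band2_drug2`.
#' @param timeline A [protocol_timeline()].
#' @param fps Sampling rate in Hz (2 Hz is the post-downsampling SV rate).
#' @param baseline Baseline SV of every vessel.
#' @param rel_amplitude Relative amplitude of every injected oscillation.
#' @param noise_sd Additive noise SD; default gives an oscillation
#'   signal-to-noise ratio of 5 (component RMS / noise SD).
#' @param induced_freq Named vector `c(band1 = , band2 = )` of induced
#'   frequencies in Hz.
#' @param spontaneous_freq List with elements `band1` and `band2`, each a
#'   length-2 frequency range in Hz for spontaneous oscillators.
#' @param animals Optional vector of per-animal vessel counts (must sum to
#'   `n_vessels`); default puts every vessel in one animal.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list with elements `series` (named list of `sv_series`) and
#'   `manifest` (a `cohort_manifest`).
#' @examples
#' coh <- generate_cohort(5, spontaneous_band1 = 2,
#'                        timeline = protocol_timeline(), seed = 1)
#' coh$manifest$vessels
#' @export
generate_cohort <- function(n_vessels,
                            spontaneous_band1 = 0, spontaneous_band2 = 0,
                            induced = NULL,
                            timeline = protocol_timeline(),
                            fps = 2, baseline = 4, rel_amplitude = 0.2,
                            noise_sd = NULL,
                            induced_freq = c(band1 = 0.17, band2 = 0.45),
                            spontaneous_freq = list(band1 = c(0.15, 0.20),
                                                    band2 = c(0.40, 0.50)),
                            animals = NULL, seed = NULL) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  stop_if_not_scalar(n_vessels, "n_vessels", positive = TRUE)
  n_vessels <- as.integer(n_vessels)
  if (is.null(noise_sd)) {
    noise_sd <- rel_amplitude * baseline / (sqrt(2) * 5)
  }

  induced_names <- c("band1_drug1", "band2_drug1", "band1_drug2", "band2_drug2")
  ind <- setNames(rep(0L, 4L), induced_names)
  if (!is.null(induced)) {
    if (is.null(names(induced)) || !all(names(induced) %in% induced_names)) {
      abort(paste0("`induced` must be a named vector with names among: ",
                   paste(induced_names, collapse = ", ")))
    }
    ind[names(induced)] <- as.integer(induced)
  }
  counts <- c(spontaneous_band1 = as.integer(spontaneous_band1),
              spontaneous_band2 = as.integer(spontaneous_band2), ind)
  if (any(counts < 0)) abort("Vessel counts must be non-negative.")
  if (sum(counts) > n_vessels) {
    abort(sprintf(
      "Inconsistent counts: %d vessels requested with roles but the cohort has only %d vessels.",
      sum(counts), n_vessels
    ))
  }
  if (is.null(animals)) animals <- n_vessels
  if (sum(animals) != n_vessels) {
    abort("`animals` (per-animal vessel counts) must sum to `n_vessels`.")
  }

  duration <- timeline_total(timeline)
  bounds <- period_bounds(timeline)
  vessel_ids <- sprintf("v%03d", seq_len(n_vessels))
  animal_ids <- rep(sprintf("animal%d", seq_along(animals)), times = animals)

  with_seed(seed, {
    # assign disjoint roles at random
    pool <- sample.int(n_vessels)
    roles <- rep("noise", n_vessels)
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    assignment <- list()
    for (nm in names(counts)) {
      idx <- if (counts[[nm]] > 0) take(counts[[nm]]) else integer()
      assignment[[nm]] <- idx
      roles[idx] <- nm
    }

    comp_rows <- list()
    for (nm in names(assignment)) {
      for (v in assignment[[nm]]) {
        band <- if (grepl("band1", nm)) "band1" else "band2"
        if (grepl("spontaneous", nm)) {
          rng <- spontaneous_freq[[band]]
          f <- runif(1, rng[1], rng[2])
          comp <- oscillatory_component(f, rel_amplitude,
                                        phase = runif(1, 0, 2 * pi),
                                        onset = 0, offset = Inf,
                                        envelope = "constant")
          period <- "all"
        } else {
          period <- if (grepl("drug1", nm)) "drug1" else "drug2"
          b <- bounds[bounds$period == period, ]
          comp <- oscillatory_component(induced_freq[[band]], rel_amplitude,
                                        phase = runif(1, 0, 2 * pi),
                                        onset = b$start, offset = b$end,
                                        envelope = "ramped")
        }
        comp_rows[[length(comp_rows) + 1L]] <-
          dplyr::mutate(comp, vessel_id = vessel_ids[v], band = band,
                        period = period, role = nm)
      }
    }
    components <- if (length(comp_rows) > 0) {
      dplyr::bind_rows(comp_rows)
    } else {
      dplyr::mutate(validate_components(NULL, fps),
                    vessel_id = character(), band = character(),
                    period = character(), role = character())
    }

    series <- vector("list", n_vessels)
    names(series) <- vessel_ids
    for (v in seq_len(n_vessels)) {
      comps <- components[components$vessel_id == vessel_ids[v],
                          c("frequency", "rel_amplitude", "phase",
                            "onset", "offset", "envelope")]
      series[[v]] <- generate_sv_series(
        if (nrow(comps) > 0) comps else NULL,
        baseline = baseline, noise_sd = noise_sd, fps = fps,
        duration = duration, seed = NULL, vessel_id = vessel_ids[v]
      )
    }

    manifest <- structure(
      list(
        seed = seed, fps = fps, baseline = baseline, noise_sd = noise_sd,
        rel_amplitude = rel_amplitude,
        timeline = timeline,
        vessels = tibble(vessel_id = vessel_ids, animal = animal_ids,
                         role = roles),
        components = components
      ),
      class = "cohort_manifest"
    )
    list(series = series, manifest = manifest)
  })
}

#' Write / read a cohort ground-truth manifest as JSON
#'
#' The manifest round-trips exactly: reading a written manifest reproduces
#' the same vessel table and component lists.
#'
#' @param manifest A `cohort_manifest` (see [generate_cohort()]).
#' @param path File path to write to / read from.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns a `cohort_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  payload <- list(
    seed = manifest$seed, fps = manifest$fps, baseline = manifest$baseline,
    noise_sd = manifest$noise_sd, rel_amplitude = manifest$rel_amplitude,
    timeline = unclass(manifest$timeline),
    vessels = manifest$vessels,
    components = dplyr::mutate(
      manifest$components,
      offset = ifelse(is.infinite(.data$offset), "Inf", as.character(.data$offset))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- as_tibble(payload$components)
  if (nrow(comps) > 0) comps$offset <- as.numeric(comps$offset)
  structure(
    list(
      seed = payload$seed, fps = payload$fps, baseline = payload$baseline,
      noise_sd = payload$noise_sd, rel_amplitude = payload$rel_amplitude,
      timeline = do.call(protocol_timeline, payload$timeline),
      vessels = as_tibble(payload$vessels),
      components = comps
    ),
    class = "cohort_manifest"
  )
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d vessels (%s), fps %g Hz, baseline SV %g\n",
              nrow(x$vessels),
              paste(names(table(x$vessels$role)), table(x$vessels$role),
                    sep = ":", collapse = ", "),
              x$fps, x$baseline))
  invisible(x)
}
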