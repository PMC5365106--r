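# broom-style tidiers for the package's result objects

#' Tidy a wavelet energy map into a long tibble
#'
#' @param x An `energy_map`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `frequency_hz`, `energy`, `in_coi`.
#' @export
tidy.energy_map <- function(x, ...) {
  tibble(
    time = rep(x$times, each = length(x$frequencies)),
    frequency_hz = rep(x$frequencies, times = length(x$times)),
    energy = as.vector(x$energy),
    in_coi = as.vector(x$coi_mask)
  )
}

#' @rdname tidy.energy_map
#' @export
glance.energy_map <- function(x, ...) {
  tibble(
    n_frequencies = length(x$frequencies), n_times = length(x$times),
    f_min = min(x$frequencies), f_max = max(x$frequencies),
    fps = x$fps, omega0 = x$omega0, normalization = x$normalization,
    coi_fraction = mean(x$coi_mask)
  )
}

#' Tidy a continuous wavelet transform into a long tibble
#'
#' @param x A `vaso_cwt`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `frequency_hz`, `modulus`, `phase`.
#' @export
tidy.vaso_cwt <- function(x, ...) {
  tibble(
    time = rep(x$times, each = length(x$frequencies)),
    frequency_hz = rep(x$frequencies, times = length(x$times)),
    modulus = as.vector(Mod(x$coefficients)),
    phase = as.vector(Arg(x$coefficients))
  )
}

#' Tidy / glance a pipeline run
#'
#' `tidy()` returns the per-vessel classification rows; `glance()` one row
#' of cohort-level detection counts.
#'
#' @param x A `vaso_run` (see [run_pipeline()]).
#' @param ... Unused.
#' @export
tidy.vaso_run <- function(x, ...) {
  x$metrics
}

#' @rdname tidy.vaso_run
#' @export
glance.vaso_run <- function(x, ...) {
  totals <- x$summary[x$summary$animal == "Total", ]
  first <- totals[1, , drop = FALSE]
  tibble(
    n_vessels = length(x$series),
    n_animals = dplyr::n_distinct(x$manifest$vessels$animal),
    m1 = first$m1, m2 = first$m2,
    n1_drug1 = totals$n1[match("drug1", totals$period)],
    n2_drug1 = totals$n2[match("drug1", totals$period)],
    n1_drug2 = totals$n1[match("drug2", totals$period)],
    n2_drug2 = totals$n2[match("drug2", totals$period)],
    seed = x$config$seed %||% NA_integer_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
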