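# Fixtures are built in code; nothing is read from disk.

# default 2 Hz SV frequency grid (0.05-0.8 Hz, 12 voices/octave)
grid2 <- frequency_grid(2)

# wrap a bare energy vector as an avg_spectrum on a given grid
make_spectrum <- function(energy, frequencies = grid2$frequencies,
                          label = NULL, omega0 = 6, voices = 12) {
  stopifnot(length(energy) == length(frequencies))
  out <- tibble::tibble(frequency_hz = frequencies, mean_energy = energy,
                        n_points = 100L)
  attr(out, "window") <- c(0, 600)
  attr(out, "label") <- label
  attr(out, "omega0") <- omega0
  attr(out, "voices") <- voices
  class(out) <- c("avg_spectrum", class(out))
  out
}

# flat background with a Gaussian bump (in log-frequency) at `center`
bump_spectrum <- function(center, height, background = 1,
                          width = 0.08, frequencies = grid2$frequencies) {
  e <- background + height * exp(-(log(frequencies / center))^2 / (2 * width^2))
  make_spectrum(e, frequencies)
}

# uniform-SV map stack (no speckle noise), vessel rows carry `vessel_sv`
# modulated by `modulation` (length = n frames)
make_vessel_map_stack <- function(ny = 40, nx = 60, vessel_rows = 18:23,
                                  vessel_sv = 8, background_sv = 2,
                                  modulation = rep(0, 24), fps = 2) {
  nt <- length(modulation)
  values <- array(background_sv, dim = c(ny, nx, nt))
  for (j in seq_len(nt)) {
    values[vessel_rows, , j] <- vessel_sv * (1 + modulation[j])
  }
  structure(
    list(values = values, valid = array(TRUE, dim = c(ny, nx, nt)),
         fps = fps, window = 5L),
    class = "sv_map_stack"
  )
}

true_vessel_mask <- function(ny = 40, nx = 60, vessel_rows = 18:23) {
  m <- matrix(FALSE, ny, nx)
  m[vessel_rows, ] <- TRUE
  m
}

# one-frequency-step agreement on a log grid
within_one_step <- function(f, f0, voices = 12) {
  abs(log2(f / f0)) <= 1 / voices + 1e-9
}
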