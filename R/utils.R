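# internal helpers shared across modules

# Evaluate code with a fully pinned RNG state; seed = NULL runs un-seeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(
    as.integer(seed), code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection"
  )
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# nearest power-of-two-ish padding length for linear convolution via FFT
pad_length <- function(n) {
  stats::nextn(n, factors = 2L)
}

# columnwise moving sum of a matrix over `k` rows (used by the SV filter)
# via cumulative sums; returns (nrow - k + 1) x ncol
running_sum <- function(m, k) {
  cs <- apply(m, 2L, cumsum)
  if (!is.matrix(cs)) cs <- matrix(cs, ncol = ncol(m))
  top <- cs[k:nrow(m), , drop = FALSE]
  if (k < nrow(m) + 1L && k > 1L) {
    below <- rbind(0, cs[seq_len(nrow(m) - k), , drop = FALSE])
    top - below
  } else if (k == 1L) {
    m
  } else {
    top
  }
}
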