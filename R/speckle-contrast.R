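#' Spatial speckle-variance (SV) map of a single frame
#'
#' Computes the speckle-variance statistic at every pixel of an intensity
#' frame: the squared window mean divided by the window sample variance,
#' \deqn{SV = \bar I^2 / \sigma^2,}
#' over a square sliding window (default 5x5, i.e. 25 pixels, moved with a
#' step of 1 pixel).  Higher flow blurs the speckle pattern, lowering the
#' local contrast and raising SV, so SV maps are bright along perfused
#' vessels.
#'
#' Border pixels where the full window does not fit, and pixels whose window
#' variance is zero (SV undefined), are marked invalid rather than padded or
#' set to infinity.
#'
#' @param frame Numeric matrix of non-negative intensities (rows = y,
#'   cols = x).
#' @param window Odd window size >= 3 (default 5).
#' @return An `sv_map`: list with `values` (matrix, `NA` where invalid),
#'   `valid` (logical matrix) and `window`.
#' @examples
#' f <- matrix(rgamma(400, shape = 4), 20, 20)
#' m <- spatial_sv(f)
#' mean(m$values[m$valid])
#' @export
spatial_sv <- function(frame, window = 5L) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    abort("`frame` must be a numeric matrix.")
  }
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 3.")
  }
  if (nrow(frame) < window || ncol(frame) < window) {
    abort("frame dimensions must be at least `window` in each direction.")
  }
  n_pix <- window^2
  # window sums of x and x^2 via separable running sums
  s1 <- t(running_sum(t(running_sum(frame, window)), window))
  s2 <- t(running_sum(t(running_sum(frame^2, window)), window))
  m <- s1 / n_pix
  v <- (s2 - n_pix * m^2) / (n_pix - 1)
  sv_core <- m^2 / v
  ny <- nrow(frame)
  nx <- ncol(frame)
  half <- (window - 1L) %/% 2L
  values <- matrix(NA_real_, ny, nx)
  valid <- matrix(FALSE, ny, nx)
  rows <- (half + 1L):(ny - half)
  cols <- (half + 1L):(nx - half)
  # guard tiny negative variances from floating-point cancellation
  ok <- v > pmax(s2, .Machine$double.xmin) * 1e-12
  values[rows, cols] <- ifelse(ok, sv_core, NA_real_)
  valid[rows, cols] <- ok
  structure(list(values = values, valid = valid, window = window),
            class = "sv_map")
}

#' @export
print.sv_map <- function(x, ...) {
  cat(sprintf("<sv_map> %d x %d px (window %d), %d valid px, SV range [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$window, sum(x$valid),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' SV maps for every frame of a stack
#'
#' Applies [spatial_sv()] to each frame, producing an SV map stack at the
#' same frame rate.
#'
#' @param stack A `frame_stack` (see [generate_speckle_stack()]).
#' @param window Odd window size >= 3.
#' @return An `sv_map_stack`: list with `values` (3-D array y
#'   \eqn{\times}{x} x \eqn{\times}{x} time), `valid` (logical array),
#'   `fps` and `window`.
#' @export
sv_map_stack <- function(stack, window = 5L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (length(stack$frames) == 0) abort("empty frame stack")
  maps <- lapply(stack$frames, spatial_sv, window = window)
  ny <- nrow(maps[[1]]$values)
  nx <- ncol(maps[[1]]$values)
  values <- array(unlist(lapply(maps, `[[`, "values")), dim = c(ny, nx, length(maps)))
  valid <- array(unlist(lapply(maps, `[[`, "valid")), dim = c(ny, nx, length(maps)))
  structure(list(values = values, valid = valid, fps = stack$fps,
                 window = window),
            class = "sv_map_stack")
}

#' Temporal block-average downsampling
#'
#' Averages `block` consecutive samples (or frames) into one, reducing the
#' rate from `fps` to `fps / block`; with the recording settings of the
#' motivating experiments (50 fps, block of 25) this yields 2 frames per
#' second, enough to satisfy the Nyquist criterion for vasomotion and
#' breathing rhythms.  A trailing partial block is discarded.  For SV map
#' stacks the average at each pixel is taken over the valid samples in the
#' block; a pixel with no valid sample in a block is invalid in the output.
#'
#' @param x A `frame_stack`, `sv_map_stack`, `sv_series`, or plain numeric
#'   vector.
#' @param block Number of consecutive samples per output sample (default 25).
#' @param ... Unused.
#' @return Same type as `x`, at `fps / block`. If fewer than `block` samples
#'   are available the result is empty, with a warning.
#' @export
temporal_downsample <- function(x, block = 25L, ...) {
  UseMethod("temporal_downsample")
}

check_block <- function(block) {
  block <- as.integer(block)
  if (block < 1L) abort("`block` must be >= 1.")
  block
}

#' @export
temporal_downsample.numeric <- function(x, block = 25L, ...) {
  block <- check_block(block)
  n_out <- length(x) %/% block
  if (n_out == 0) {
    warn("fewer samples than `block`: empty output")
    return(numeric(0))
  }
  colMeans(matrix(x[seq_len(n_out * block)], nrow = block))
}

#' @export
temporal_downsample.sv_series <- function(x, block = 25L, ...) {
  block <- check_block(block)
  fps <- attr(x, "fps")
  sv <- temporal_downsample.numeric(x$sv, block)
  new_fps <- fps / block
  new_sv_series(time = (seq_along(sv) - 1) / new_fps, sv = sv, fps = new_fps,
                vessel_id = attr(x, "vessel_id"))
}

#' @export
temporal_downsample.frame_stack <- function(x, block = 25L, ...) {
  block <- check_block(block)
  n_out <- length(x$frames) %/% block
  if (n_out == 0) {
    warn("fewer frames than `block`: empty output")
    return(new_frame_stack(list(), x$fps / block))
  }
  frames <- lapply(seq_len(n_out), function(j) {
    Reduce(`+`, x$frames[((j - 1) * block + 1):(j * block)]) / block
  })
  new_frame_stack(frames, x$fps / block)
}

#' @export
temporal_downsample.sv_map_stack <- function(x, block = 25L, ...) {
  block <- check_block(block)
  nt <- dim(x$values)[3]
  n_out <- nt %/% block
  if (n_out == 0) {
    warn("fewer frames than `block`: empty output")
    return(structure(list(values = x$values[, , 0, drop = FALSE],
                          valid = x$valid[, , 0, drop = FALSE],
                          fps = x$fps / block, window = x$window),
                     class = "sv_map_stack"))
  }
  ny <- dim(x$values)[1]
  nx <- dim(x$values)[2]
  values <- array(NA_real_, c(ny, nx, n_out))
  valid <- array(FALSE, c(ny, nx, n_out))
  for (j in seq_len(n_out)) {
    idx <- ((j - 1) * block + 1):(j * block)
    vsum <- matrix(0, ny, nx)
    vcnt <- matrix(0L, ny, nx)
    for (k in idx) {
      ok <- x$valid[, , k]
      vv <- x$values[, , k]
      vsum[ok] <- vsum[ok] + vv[ok]
      vcnt <- vcnt + ok
    }
    ok_out <- vcnt > 0L
    out <- matrix(NA_real_, ny, nx)
    out[ok_out] <- vsum[ok_out] / vcnt[ok_out]
    values[, , j] <- out
    valid[, , j] <- ok_out
  }
  structure(list(values = values, valid = valid, fps = x$fps / block,
                 window = x$window),
            class = "sv_map_stack")
}

#' Mean SV frame of an SV map stack
#'
#' Pixelwise mean over time of the valid SV samples; used as the static
#' image on which regions of interest are drawn and vessels are masked.
#'
#' @param maps An `sv_map_stack`.
#' @return An `sv_map`.
#' @export
mean_sv_map <- function(maps) {
  stopifnot(inherits(maps, "sv_map_stack"))
  cnt <- apply(maps$valid, c(1, 2), sum)
  tot <- apply(ifelse(maps$valid, maps$values, 0), c(1, 2), sum)
  ok <- cnt > 0
  values <- matrix(NA_real_, nrow(ok), ncol(ok))
  values[ok] <- tot[ok] / cnt[ok]
  structure(list(values = values, valid = ok, window = maps$window),
            class = "sv_map")
}
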