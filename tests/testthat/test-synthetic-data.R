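# Synthetic SV series, pressure signals, speckle stacks and cohorts.

test_that("a component-free, noise-free series is the constant baseline", {
  s <- generate_sv_series(NULL, baseline = 4, noise_sd = 0, fps = 2,
                          duration = 30)
  expect_equal(nrow(s), 60)
  expect_true(all(s$sv == 4))
  expect_equal(attr(s, "fps"), 2)
})

test_that("injected tones dominate the discrete power spectrum at the nearest FFT bin", {
  # FFT oracle: the maximum of |FFT|^2 (excluding DC) must fall on the bin
  # nearest each injected frequency
  for (f0 in c(0.17, 0.3, 0.46)) {
    s <- generate_sv_series(oscillatory_component(f0, 0.2), baseline = 4,
                            noise_sd = 0, fps = 2, duration = 600)
    spec <- Mod(stats::fft(s$sv - mean(s$sv)))^2
    half <- 2:(length(spec) %/% 2)
    kmax <- half[which.max(spec[half])] - 1
    f_found <- kmax * 2 / length(spec)
    expect_equal(f_found, f0, tolerance = 2 / length(spec) / f0)
  }
})

test_that("series generation is bit-reproducible given a seed", {
  a <- generate_sv_series(oscillatory_component(0.2, 0.1), noise_sd = 0.2,
                          fps = 2, duration = 100, seed = 7)
  b <- generate_sv_series(oscillatory_component(0.2, 0.1), noise_sd = 0.2,
                          fps = 2, duration = 100, seed = 7)
  d <- generate_sv_series(oscillatory_component(0.2, 0.1), noise_sd = 0.2,
                          fps = 2, duration = 100, seed = 8)
  expect_identical(a$sv, b$sv)
  expect_false(identical(a$sv, d$sv))
})

test_that("components at or above Nyquist are refused", {
  expect_error(
    generate_sv_series(oscillatory_component(1.0, 0.2), fps = 2, duration = 10),
    "Nyquist"
  )
})

test_that("onset/offset and the ramped envelope confine the oscillation", {
  comp <- oscillatory_component(0.2, 0.5, onset = 100, offset = 200,
                                envelope = "ramped")
  s <- generate_sv_series(comp, baseline = 4, noise_sd = 0, fps = 2,
                          duration = 300)
  expect_true(all(s$sv[s$time < 100] == 4))           # silent before onset
  expect_true(all(s$sv[s$time >= 200] == 4))          # silent after offset
  mid <- s$sv[s$time >= 160 & s$time < 170]
  expect_gt(max(abs(mid - 4)), 1)                     # active in between
  ramp <- abs(s$sv[s$time >= 100 & s$time < 130] - 4)
  full <- max(abs(s$sv - 4))
  expect_lt(max(ramp), full)                          # ramp attenuates onset
})

test_that("component validation enforces the domain invariants", {
  expect_error(oscillatory_component(-1, 0.2), "frequency")
  expect_error(oscillatory_component(0.2, 1.2), "rel_amplitude")
  expect_error(oscillatory_component(0.2, 0.2, onset = 10, offset = 5), "onset")
})

test_that("a noiseless pressure signal holds exactly three spectral lines", {
  p <- generate_pressure_signal(duration = 20 * 60, fps = 50, noise = "none")
  spec <- Mod(stats::fft(p$sv - mean(p$sv)))
  n <- length(spec)
  bins <- round(c(0.5, 1, 6.4) * n / 50) + 1          # exact-bin frequencies
  line_power <- sum(spec[c(bins, n + 2 - bins)]^2)
  expect_gt(line_power / sum(spec^2), 1 - 1e-12)
  # and amplitudes of zero give a constant baseline
  p0 <- generate_pressure_signal(duration = 60, fps = 50,
                                 components = systemic_components(0),
                                 noise = "none")
  expect_true(all(p0$sv == 100))
})

test_that("pressure generation is reproducible and pink noise slopes as 1/f", {
  a <- generate_pressure_signal(duration = 120, fps = 50, seed = 3)
  b <- generate_pressure_signal(duration = 120, fps = 50, seed = 3)
  expect_identical(a$sv, b$sv)
  # isolate the noise and compare band powers: 1/f noise concentrates at
  # low frequencies
  clean <- generate_pressure_signal(duration = 600, fps = 50, noise = "none")
  noisy <- generate_pressure_signal(duration = 600, fps = 50, snr = 5, seed = 4)
  noise <- noisy$sv - clean$sv
  spec <- Mod(stats::fft(noise))^2
  n <- length(spec)
  f <- (seq_len(n) - 1) * 50 / n
  low <- sum(spec[f >= 0.05 & f <= 0.5])
  high <- sum(spec[f >= 5 & f <= 5.45])   # equally wide band, 100x higher
  expect_gt(low, 10 * high)
})

test_that("speckle stacks reproduce target SV fields through the contrast estimator", {
  # Gamma-moment identity + small-sample calibration, Monte-Carlo tolerance:
  # vessel at SV 8 on background 2, no oscillation
  v <- vessel_geometry(cbind(x = c(2, 45), y = c(24, 24)), width = 13,
                       baseline_sv = 8)
  st <- generate_speckle_stack(v, background_sv = 2, frame_shape = c(48, 48),
                               fps = 10, duration = 2, seed = 5)
  maps <- sv_map_stack(st$stack)
  msv <- mean_sv_map(maps)
  truth <- st$manifest$vessels[[1]]$mask
  # interior vessel pixels: windows fully inside the vessel
  interior <- truth
  for (i in 1:6) interior <- vasowave:::erode3(interior)
  background <- !truth
  for (i in 1:3) background <- vasowave:::erode3(background)
  expect_equal(mean(msv$values[interior & msv$valid]), 8, tolerance = 0.05)
  expect_equal(mean(msv$values[background & msv$valid]), 2, tolerance = 0.05)
})

test_that("a zero-duration stack request yields an empty stack and manifest", {
  v <- vessel_geometry(cbind(x = c(2, 20), y = c(10, 10)), width = 4,
                       baseline_sv = 8)
  st <- generate_speckle_stack(v, duration = 0, frame_shape = c(24, 24))
  expect_length(st$stack$frames, 0)
  expect_length(st$manifest$vessels, 0)
})

test_that("non-positive target SV is rejected", {
  v <- vessel_geometry(cbind(x = c(2, 20), y = c(10, 10)), width = 4,
                       baseline_sv = 8)
  comp <- list(v1 = tibble::tibble(
    frequency = 1, rel_amplitude = 0.999999, phase = -pi / 2, onset = 0,
    offset = Inf, envelope = "constant"
  ))
  # amplitude ~1 drives vessel SV to ~0 at the trough -> below calibration range
  expect_error(
    generate_speckle_stack(v, components = comp, frame_shape = c(24, 24),
                           fps = 10, duration = 1, seed = 1),
    "SV"
  )
})

test_that("stack intensities round-trip through 16-bit TIFF", {
  v <- vessel_geometry(cbind(x = c(2, 20), y = c(10, 10)), width = 4,
                       baseline_sv = 8)
  st <- generate_speckle_stack(v, frame_shape = c(24, 24), fps = 10,
                               duration = 0.5, seed = 6)
  path <- withr::local_tempfile(fileext = ".tiff")
  gain <- write_stack_tiff(st$stack, path)
  back <- read_stack_tiff(path, fps = 10, gain = gain)
  expect_length(back$frames, length(st$stack$frames))
  # 16-bit quantization: relative error bounded by ~2^-16 of the range
  rel <- max(abs(back$frames[[1]] - st$stack$frames[[1]])) / gain
  expect_lt(rel, 1 / 65535)
})

test_that("cohort role assignment matches the requested design exactly", {
  coh <- generate_cohort(81, spontaneous_band1 = 8, seed = 1)
  tab <- table(coh$manifest$vessels$role)
  expect_equal(unname(tab[["spontaneous_band1"]]), 8)
  expect_equal(unname(tab[["noise"]]), 73)
  comps <- coh$manifest$components
  expect_equal(nrow(comps), 8)
  expect_true(all(comps$frequency >= 0.15 & comps$frequency <= 0.2))
  expect_true(all(comps$onset == 0 & is.infinite(comps$offset)))
  # every vessel id appears exactly once in the manifest
  expect_equal(sort(coh$manifest$vessels$vessel_id), sort(names(coh$series)))
  expect_false(any(duplicated(coh$manifest$vessels$vessel_id)))
})

test_that("an all-noise cohort has no components and inconsistent counts fail", {
  coh <- generate_cohort(4, seed = 2)
  expect_equal(nrow(coh$manifest$components), 0)
  expect_true(all(coh$manifest$vessels$role == "noise"))
  expect_error(generate_cohort(5, spontaneous_band1 = 4, spontaneous_band2 = 3),
               "Inconsistent")
})

test_that("the ground-truth manifest round-trips through JSON", {
  coh <- generate_cohort(6, spontaneous_band1 = 2,
                         induced = c(band1_drug1 = 2), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(coh$manifest, path)
  back <- read_manifest(path)
  expect_equal(back$vessels, coh$manifest$vessels)
  expect_equal(back$components, coh$manifest$components)
  expect_equal(back$timeline, coh$manifest$timeline)
  expect_equal(back$noise_sd, coh$manifest$noise_sd)
})

test_that("cohort generation is deterministic given the seed", {
  a <- generate_cohort(3, spontaneous_band1 = 1, seed = 9)
  b <- generate_cohort(3, spontaneous_band1 = 1, seed = 9)
  expect_identical(purrr::map(a$series, "sv"), purrr::map(b$series, "sv"))
  expect_equal(a$manifest$components, b$manifest$components)
})
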