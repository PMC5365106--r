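# Peak detection, noise background, energy/prominence ratios, vessel
# classification, cohort summaries and the paired frequency comparison.

b1 <- band(0.1, 0.3, "band1")

test_that("a Gaussian bump on a flat background peaks at the nearest grid point", {
  sp <- bump_spectrum(center = 0.17, height = 3)
  pk <- find_prominent_peak(sp, b1)
  nearest <- sp$frequency_hz[which.min(abs(sp$frequency_hz - 0.17))]
  expect_equal(pk$f_peak, nearest)
  expect_equal(pk$e_background, 1, tolerance = 0.05)
  expect_equal(pk$prominence, pk$e_peak - pk$e_background)
})

test_that("monotone in-band spectra hold no peak and edge maxima do not count", {
  sp <- make_spectrum(seq_along(grid2$frequencies))  # strictly increasing
  expect_null(find_prominent_peak(sp, b1))
  # a maximum exactly at the band edge is not an interior peak
  e <- rep(1, length(grid2$frequencies))
  edge <- which.min(abs(grid2$frequencies - 0.1))
  e[edge] <- 5
  expect_null(find_prominent_peak(make_spectrum(e), b1))
})

test_that("equal-prominence peaks tie toward the lower frequency", {
  # two equal spikes three grid steps apart: each falls inside the other's
  # +/-20% background exclusion, so both see the identical flat baseline
  # and their prominences tie exactly
  e <- rep(1, length(grid2$frequencies))
  k1 <- which.min(abs(grid2$frequencies - 0.133))
  k2 <- k1 + 3
  e[c(k1, k2)] <- 4
  pk <- find_prominent_peak(make_spectrum(e), b1)
  expect_equal(pk$f_peak, grid2$frequencies[k1])
})

test_that("the background is the peak-excluded in-band median", {
  # flat spectrum of value 3 with one spike -> background 3
  e <- rep(3, length(grid2$frequencies))
  k <- which.min(abs(grid2$frequencies - 0.2))
  e[k] <- 10
  expect_equal(estimate_background(make_spectrum(e), b1, 0.2), 3)
  # linear-in-log-f background plus bump: recovered within 10% at band center
  f <- grid2$frequencies
  base <- 2 + 0.8 * log(f / 0.17)
  e2 <- base + 5 * exp(-(log(f / 0.17))^2 / (2 * 0.05^2))
  bg <- estimate_background(make_spectrum(e2), b1, 0.17)
  expect_equal(bg, 2, tolerance = 0.1)
  # tiny band forces the whole-band-median fallback, with a warning
  tiny <- band(0.15, 0.19, "tiny")
  expect_warning(bg2 <- estimate_background(make_spectrum(e), tiny, 0.17),
                 "whole-band")
  expect_gt(bg2, 0)
})

test_that("energy ratio follows its defining arithmetic", {
  resp <- bump_spectrum(0.17, 4)    # peak energy 5 at ~0.17 on background 1
  ctrl <- make_spectrum(rep(4, length(grid2$frequencies)))
  expect_equal(energy_ratio(resp, ctrl, b1), find_prominent_peak(resp, b1)$e_peak / 4,
               tolerance = 1e-12)
  # identical spectra give exactly 1 at the shared peak
  expect_equal(energy_ratio(resp, resp, b1), 1)
  # doubling the response doubles E
  resp2 <- make_spectrum(2 * resp$mean_energy)
  expect_equal(energy_ratio(resp2, resp, b1), 2)
  # no response peak -> missing
  flat <- make_spectrum(rep(1, length(grid2$frequencies)))
  expect_true(is.na(energy_ratio(flat, ctrl, b1)))
  # zero control energy -> undefined with a warning
  zero <- make_spectrum(rep(0, length(grid2$frequencies)))
  expect_warning(out <- energy_ratio(resp, zero, b1), "control")
  expect_true(is.na(out))
})

test_that("a response bump of 5.0 against control 4.0 gives E = 1.25", {
  f <- grid2$frequencies
  k <- which.min(abs(f - 0.17))
  er <- rep(1, length(f)); er[k] <- 5
  ec <- rep(4, length(f))
  expect_equal(energy_ratio(make_spectrum(er), make_spectrum(ec), b1), 1.25)
})

test_that("prominence ratio compares each spectrum's own peak and respects the boundary", {
  f <- grid2$frequencies
  k1 <- which.min(abs(f - 0.15))
  k2 <- which.min(abs(f - 0.25))
  er <- rep(1, length(f)); er[k2] <- 3.2   # response prominence 2.2 at 0.25
  ec <- rep(1, length(f)); ec[k1] <- 3.0   # control prominence 2.0 at 0.15
  resp <- make_spectrum(er)
  ctrl <- make_spectrum(ec)
  expect_equal(prominence_ratio(resp, ctrl, b1), 1.1)
  # a ratio exactly AT the threshold is NOT counted as increased activity
  # (binary-exact prominences 2.25 / 2.0 with threshold 1.125)
  er2 <- rep(1, length(f)); er2[k2] <- 3.25
  m <- classify_vessel(list(control = ctrl, drug1 = make_spectrum(er2)),
                       threshold = 1.125, smooth_bw = 0)
  expect_equal(m$prominence_ratio[m$band == "band1" & m$period == "drug1"], 1.125)
  expect_false(m$increased[m$band == "band1" & m$period == "drug1"])
  # identical spectra give exactly 1
  expect_equal(prominence_ratio(resp, resp, b1), 1)
})

test_that("ratios and flags are invariant under a common energy rescaling", {
  resp <- bump_spectrum(0.18, 4)
  ctrl <- bump_spectrum(0.15, 1.5)
  for (c in c(1e-3, 7, 1e4)) {
    respc <- make_spectrum(c * resp$mean_energy)
    ctrlc <- make_spectrum(c * ctrl$mean_energy)
    expect_equal(energy_ratio(respc, ctrlc, b1), energy_ratio(resp, ctrl, b1),
                 tolerance = 1e-12)
    expect_equal(prominence_ratio(respc, ctrlc, b1),
                 prominence_ratio(resp, ctrl, b1), tolerance = 1e-12)
    m1 <- classify_vessel(list(control = ctrl, drug1 = resp), smooth_bw = 0)
    m2 <- classify_vessel(list(control = ctrlc, drug1 = respc), smooth_bw = 0)
    expect_equal(m1$spontaneous, m2$spontaneous)
    expect_equal(m1$increased, m2$increased)
    expect_equal(m1$induced, m2$induced)
  }
})

test_that("classification applies the detection rules per band and period", {
  flatten <- function(x) rep(x, length(grid2$frequencies))
  # control peak 20% above background -> spontaneous
  ctrl <- bump_spectrum(0.2, 0.2 * 1)     # e_peak = 1.2, background 1
  m <- classify_vessel(list(control = ctrl), smooth_bw = 0)
  expect_true(m$spontaneous[m$band == "band1"][1])
  # drug peak 3x background in a control-silent vessel -> induced
  # (control carries a faint deterministic ripple, as real spectra do)
  ctrl2 <- make_spectrum(1 + 0.01 * sin(seq_along(grid2$frequencies)))
  resp2 <- bump_spectrum(0.17, 2)         # peak 3 on background 1
  m2 <- classify_vessel(list(control = ctrl2, drug1 = resp2), smooth_bw = 0)
  row <- m2[m2$band == "band1" & m2$period == "drug1", ]
  expect_true(row$above_background)
  expect_true(row$induced)
  expect_true(row$increased)
  # spontaneous vessels are not "induced" even when responsive
  m3 <- classify_vessel(list(control = ctrl, drug1 = resp2), smooth_bw = 0)
  row3 <- m3[m3$band == "band1" & m3$period == "drug1", ]
  expect_false(row3$induced)
  # missing response spectra give missing flags, not FALSE
  m4 <- classify_vessel(list(control = ctrl2), smooth_bw = 0)
  expect_true(all(is.na(m4$increased)))
  expect_true(all(is.na(m4$induced)))
})

test_that("raising the threshold never increases the detection counts", {
  withr::with_seed(41, {
    spectra <- purrr::map(1:12, function(i) {
      list(control = make_spectrum(1 + 0.5 * runif(length(grid2$frequencies))),
           drug1 = make_spectrum(1 + 0.8 * runif(length(grid2$frequencies))))
    })
    counts <- purrr::map_dfr(c(1.05, 1.1, 1.3, 2), function(thr) {
      m <- dplyr::bind_rows(purrr::imap(spectra, function(sp, i) {
        classify_vessel(sp, threshold = thr, smooth_bw = 0,
                        vessel_id = paste0("v", i))
      }))
      tibble::tibble(
        thr = thr,
        m1 = sum(m$spontaneous[m$band == "band1"], na.rm = TRUE),
        n1 = sum(m$increased[m$band == "band1"], na.rm = TRUE)
      )
    })
    expect_true(all(diff(counts$m1) <= 0))
    expect_true(all(diff(counts$n1) <= 0))
  })
})

test_that("cohort summaries count and average over the increased vessels only", {
  # all-quiet cohort: P = 1 everywhere -> n = 0 and empty E/f columns
  sp <- bump_spectrum(0.2, 2)
  quiet <- dplyr::bind_rows(purrr::map(1:3, function(i) {
    classify_vessel(list(control = sp, drug1 = sp), smooth_bw = 0,
                    vessel_id = paste0("v", i))
  }))
  s <- summarize_cohort(quiet)
  tot <- s[s$animal == "Total", ]
  expect_equal(tot$n1, 0)
  expect_true(is.na(tot$E1_mean))
  # two animals merge additively into the Total row
  # (controls carry a faint ripple, as any real averaged spectrum does)
  ctrl <- make_spectrum(1 + 0.01 * sin(seq_along(grid2$frequencies)))
  resp <- bump_spectrum(0.17, 2)
  mets <- dplyr::bind_rows(purrr::map(1:5, function(i) {
    classify_vessel(list(control = ctrl, drug1 = if (i <= 2) resp else ctrl),
                    smooth_bw = 0, vessel_id = paste0("v", i))
  }))
  vessels <- tibble::tibble(vessel_id = paste0("v", 1:5),
                            animal = c("a1", "a1", "a1", "a2", "a2"))
  s2 <- summarize_cohort(mets, vessels)
  tot2 <- s2[s2$animal == "Total", ]
  per <- s2[s2$animal != "Total", ]
  expect_equal(tot2$N, sum(per$N))
  expect_equal(tot2$n1, sum(per$n1))
  expect_equal(tot2$m1, sum(per$m1))
  expect_equal(tot2$n1, 2)
  expect_equal(tot2$f1_mean, find_prominent_peak(resp, b1)$f_peak)
})

test_that("cohort-level spontaneous counts recover a constructed 8-of-81 design", {
  # constructed spectra: 8 vessels carry a high-SNR band-1 bump, 73 are flat
  withr::with_seed(42, {
    mets <- dplyr::bind_rows(purrr::map(1:81, function(i) {
      e <- if (i <= 8) {
        bump_spectrum(runif(1, 0.15, 0.2), 2)$mean_energy
      } else {
        rep(1, length(grid2$frequencies)) + 0.01 * rnorm(length(grid2$frequencies))
      }
      classify_vessel(list(control = make_spectrum(e)), smooth_bw = 0,
                      vessel_id = sprintf("v%02d", i))
    }))
    s <- summarize_cohort(mets)
    expect_equal(s$m1[s$animal == "Total"], 8)
  })
})

test_that("the paired frequency comparison behaves as a calibrated t-test", {
  # constant shift with tiny noise is detected
  withr::with_seed(43, {
    f1 <- rnorm(20, 0.17, 0.005)
    out <- compare_frequencies(f1, f1 + 0.1 + rnorm(20, 0, 0.001))
    expect_lt(out$p_value, 0.05)
    expect_equal(out$n_pairs, 20)
  })
  # identical vectors take the degenerate path
  out2 <- compare_frequencies(c(0.17, 0.2, 0.15), c(0.17, 0.2, 0.15))
  expect_equal(out2$p_value, 1)
  expect_match(out2$note, "zero")
  # fewer than two complete pairs is undefined
  out3 <- compare_frequencies(c(0.17, NA), c(0.18, 0.2))
  expect_true(is.na(out3$p_value))
  expect_match(out3$note, "fewer")
})

test_that("the paired t-test holds its nominal type-I error rate", {
  withr::with_seed(44, {
    rej <- mean(replicate(1000, {
      compare_frequencies(rnorm(30, 0.17, 0.03), rnorm(30, 0.17, 0.03))$p_value < 0.05
    }))
    expect_gte(rej, 0.03)
    expect_lte(rej, 0.07)
  })
})
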