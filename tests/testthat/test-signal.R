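test_that("the analyzable band and filter edges follow the frame rate", {
  expect_equal(analyzable_band_hz(24), 12)
  expect_equal(unname(band_edges_hz(filter_spec(), 24)),
               c(0.36, 0.48, 4.8, 6.0))
  expect_error(filter_spec(fstop1 = 0.05, fpass1 = 0.04), "band edges")
})

test_that("the designed bandpass meets its magnitude template", {
  filt <- design_bandpass(filter_spec(), 24)
  # passband: 2 Hz within the allowed ripple of unity
  r <- filter_response(filt, c(0.1, 2, 1.5))
  expect_lt(abs(r$magnitude_db[2]), filter_spec()$apass_db)
  expect_lt(abs(r$magnitude_db[3]), filter_spec()$apass_db)
  # deep stopband at 0.1 Hz
  expect_lt(r$magnitude_db[1], -95)
  expect_gte(filt$achieved[["stop_db"]], 95)
  expect_lte(filt$achieved[["pass_db"]], 5)
})

test_that("filters longer than the signal are refused with the minimum length", {
  expect_error(design_bandpass(filter_spec(), 24, max_length = 240),
               "at least")
  filt <- design_bandpass(relaxed_spec(), 24, max_length = 240)
  expect_lte(length(filt$taps), 240)
  expect_error(bandpass_waveform(rnorm(50), filt), "shorter than")
})

test_that("filtering removes DC and out-of-band components, keeps passband", {
  filt <- design_bandpass(filter_spec(), 24)
  n <- 2880
  t <- (0:(n - 1)) / 24
  # constant input -> essentially zero
  out <- bandpass_waveform(rep(0.6, n), filt)
  expect_lt(max(abs(out)), 1e-8)
  expect_lt(abs(mean(bandpass_waveform(0.6 + 0.01 * sin(2 * pi * 1.5 * t), filt))),
            1e-5)
  # steady-state region (past the filter length)
  ss <- seq(length(filt$taps) + 1, n)
  # 0.2 Hz (stopband) amplitude 0.05: residual rms under 1% of input rms
  low <- 0.05 * sin(2 * pi * 0.2 * t)
  out_low <- bandpass_waveform(low, filt)
  expect_lt(sqrt(mean(out_low[ss]^2)) / sqrt(mean(low^2)), 0.01)
  # 1.5 Hz (passband) amplitude 0.01 passes at unit gain
  mid <- 0.01 * sin(2 * pi * 1.5 * t)
  out_mid <- bandpass_waveform(mid, filt)
  expect_equal(max(abs(out_mid[ss])), 0.01, tolerance = 0.02)
})

test_that("cycles come from prominent peaks with spacing-derived frequency", {
  fs <- 24
  t <- (0:(48 * fs - 1)) / fs
  x <- 0.01 * sin(2 * pi * 1.5 * t)
  cyc <- detect_cycles(x, fs)
  expect_equal(nrow(cyc), 71)
  expect_true(all(cyc$frequency == 1.5))
  expect_equal(diff(attr(cyc, "peaks")), rep(16, 71))
  # prominence of a sine is its peak-to-trough: 0.004 < 0.005 fails
  expect_equal(nrow(detect_cycles(0.002 * sin(2 * pi * 1.5 * t), fs)), 0)
  expect_equal(nrow(detect_cycles(rep(0, 100), fs)), 0)
})

test_that("cycle frequencies are scale-invariant, areas scale linearly", {
  set.seed(5)
  fs <- 24
  t <- (0:(60 * fs - 1)) / fs
  x <- 0.02 * sin(2 * pi * 1.8 * t) + 0.003 * rnorm(length(t))
  c1 <- detect_cycles(x, fs)
  # same acceptance set when the prominence threshold scales with the signal
  c3 <- detect_cycles(3 * x, fs, min_prominence = 3 * 0.005)
  expect_equal(c3$frequency, c1$frequency)
  expect_equal(c3$area, 3 * c1$area, tolerance = 1e-12)
  expect_true(all(c1$frequency > 0 & c1$frequency <= fs / 2))
})

test_that("plateau peaks register once, at their leftmost sample", {
  x <- c(0, 1, 2, 2, 2, 1, 0, 1, 3, 1, 0)
  cyc <- detect_cycles(x, 24, min_prominence = 0.5)
  expect_equal(attr(cyc, "peaks"), c(3, 9))
})

test_that("movement summary filters the pass range and bins areas", {
  cyc <- tibble::tibble(frequency = c(1.15, 1.25, 0.3),
                        area = c(2.0, 1.5, 9.9),
                        area_pct = 100 * c(2.0, 1.5, 9.9))
  s <- summarize_movement(cyc)
  expect_equal(s$mean_freq, 1.2)
  expect_equal(s$n_cycles, 2L)
  expect_equal(s$bin_1.1_1.3, 100 * 3.5)   # bins carry percent units
  expect_equal(sum(s[, grep("^bin_", names(s))]), 100 * 3.5)
  # a single retained cycle has sd 0 by convention
  s1 <- summarize_movement(tibble::tibble(frequency = 2, area = 0.7,
                                          area_pct = 70))
  expect_equal(s1$mean_freq, 2)
  expect_equal(s1$sd_freq, 0)
  expect_warning(s0 <- summarize_movement(tibble::tibble(frequency = 0.2,
                                                         area = 1,
                                                         area_pct = 100)),
                 "flagged")
  expect_false(s0$valid)
  expect_equal(s0$n_cycles, 0L)
})

test_that("bin areas conserve the retained sub-4.7 Hz cycle area", {
  set.seed(8)
  cyc <- tibble::tibble(frequency = runif(200, 0.1, 6),
                        area = rexp(200, 10))
  cyc$area_pct <- 100 * cyc$area
  s <- summarize_movement(cyc)
  retained <- cyc$frequency >= 0.5 & cyc$frequency < 4.7
  expect_equal(sum(s[, grep("^bin_", names(s))]),
               sum(cyc$area_pct[retained]), tolerance = 1e-9)
  expect_true(s$mean_freq >= 0.5 && s$mean_freq <= 4.9)
})

test_that("the full chain recovers a simulated 1.5 Hz natural frequency", {
  tr <- waveform_truth(1.5, amplitude = 0.01, duration_s = 120, fps = 24)
  w <- simulate_waveform(tr, seed = 21)
  filt <- design_bandpass(filter_spec(), 24)
  s <- summarize_movement(detect_cycles(bandpass_waveform(w, filt), 24))
  expect_equal(s$mean_freq, 1.5, tolerance = 0.05 / 1.5)
})

test_that("analyze_movement summarizes each plot and parses identities", {
  tr1 <- waveform_truth(1.5, amplitude = 0.012, duration_s = 120, fps = 24)
  tr2 <- waveform_truth(2.5, amplitude = 0.03, duration_s = 120, fps = 24)
  wf <- tibble::tibble(
    frame = rep(1:2880, 2), time_s = rep((0:2879) / 24, 2),
    plot = rep(c("Gopher_oat_4A", "Linkert_wheat_1B"), each = 2880),
    value = c(simulate_waveform(tr1, 1), simulate_waveform(tr2, 2)))
  class(wf) <- c("waveform_tbl", class(wf))
  attr(wf, "fps") <- 24
  out <- analyze_movement(wf)
  expect_equal(nrow(out), 2)
  expect_equal(out$cultivar, c("Gopher", "Linkert"))
  expect_equal(out$mean_freq, c(1.5, 2.5), tolerance = 0.05)
})
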