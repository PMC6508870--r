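test_that("the zero-lag filter has unit DC gain and no phase", {
  fs <- 4000
  x <- rep(3.7, 500)
  expect_equal(zero_lag_lowpass(x, fs, 150, 4), x, tolerance = 1e-9)

  # zero-phase symmetry: filtering a reversed signal reverses the output
  set.seed(1)
  y <- cumsum(rnorm(800))
  f1 <- zero_lag_lowpass(y, fs, 150, 4)
  f2 <- rev(zero_lag_lowpass(rev(y), fs, 150, 4))
  expect_equal(f1, f2, tolerance = 1e-6)

  # amplitude at the cutoff: two passes of a half-order Butterworth give
  # |H|^2 = 1/2
  fs <- 1e5
  t <- seq(0, 0.5, by = 1 / fs)
  s <- sin(2 * pi * 5000 * t)
  sf <- zero_lag_lowpass(s, fs, 5000, 4)
  core <- seq(round(0.2 * fs), round(0.3 * fs))
  ratio <- max(abs(sf[core])) / 1
  expect_lt(abs(ratio - 0.5), 0.02)

  # near-idempotence on an already band-limited signal
  s_low <- sin(2 * pi * 20 * seq(0, 1, by = 1 / 4000))
  f1 <- zero_lag_lowpass(s_low, 4000, 150, 4)
  f2 <- zero_lag_lowpass(f1, 4000, 150, 4)
  core <- 500:3500
  expect_lt(max(abs(f1[core] - f2[core])), 0.01)

  expect_error(zero_lag_lowpass(s_low, 4000, 2500, 4), "Nyquist")
  expect_error(zero_lag_lowpass(rnorm(10), 4000, 150, 4), "too short")
  expect_error(zero_lag_lowpass(s_low, 4000, 150, 3), "even")
})

test_that("impact onset is the first sample strictly above threshold", {
  # step 0 -> 300 N at sample 1000
  f <- c(rep(0, 999), rep(300, 2001))
  tr <- force_trace(f, fs = 1e6)
  on <- detect_impact_onset(tr, threshold_N = 200, baseline_s = 1e-4)
  expect_equal(on$index, 1000)

  expect_error(detect_impact_onset(force_trace(rep(0, 3000), fs = 1e6)),
               "no impact")

  # haversine pulse: onset equals a brute-force linear scan above baseline
  pulse <- generate_load_pulse(peak_N = 3500, rise_s = 0.0025,
                               duration_s = 0.02, noise_sd_N = 0)
  on <- detect_impact_onset(pulse, threshold_N = 200)
  scan <- which(pulse$force - 152 > 200)[1]
  expect_equal(on$index, scan)
  expect_equal(on$baseline, 152)

  # monotone in the threshold
  on2 <- detect_impact_onset(pulse, threshold_N = 500)
  expect_gt(on2$index, on$index)
})

test_that("windowing cuts synchronized force and marker segments", {
  pulse <- generate_load_pulse()
  on <- detect_impact_onset(pulse)
  # markers on the 4 kHz grid spanning the trace
  nt <- floor(0.020 * 4000) + 1
  arr <- array(rnorm(nt * 3 * 2, sd = 1e-4), c(nt, 3, 2),
               dimnames = list(NULL, NULL, c("A", "B")))
  mk <- marker_trajectories(arr, fs = 4000)

  w <- align_and_window(pulse, mk, on, window_s = 0.005)
  # 21 marker frames when the onset falls between frames too
  expect_equal(dim(w$markers$data)[1],
               sum(mk$times >= on$time & mk$times <= on$time + 0.005))
  expect_equal(length(w$force$force), 5001)
  # baseline-subtracted: the first windowed sample just exceeds 200 N
  expect_gt(w$force$force[1], 200)
  expect_lt(w$force$force[1] - 200, 1)
  # times relative to onset
  expect_gte(w$markers$times[1], 0)
  expect_lte(max(w$markers$times), 0.005 + 1e-12)

  # onset exactly on a marker frame -> floor(0.005 * 4000) + 1 = 21 frames
  w2 <- align_and_window(pulse, mk, list(time = mk$times[30], baseline = 152),
                         window_s = 0.005)
  expect_equal(dim(w2$markers$data)[1], 21)

  expect_error(align_and_window(pulse, mk, on, window_s = 0.5),
               "past the end")
})
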