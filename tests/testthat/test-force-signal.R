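test_that("force_trace validates its invariants and round-trips through CSV", {
  expect_error(force_trace(1), "at least 2 samples")
  expect_error(force_trace(c(1, NA)), "finite")
  expect_error(force_trace(c(1, 2), sample_rate = 0), "positive")

  tr <- force_trace(c(1, 2, 3), sample_rate = 500, t0 = 0.2,
    meta = list(participant = "P01")
  )
  expect_equal(trace_times(tr), c(0.2, 0.202, 0.204))
  expect_equal(trace_duration(tr), 0.004)

  path <- file.path(withr::local_tempdir(), "trace.csv")
  write_force_trace(tr, path)
  back <- read_force_trace(path)
  expect_equal(back$force, tr$force)
  expect_equal(back$sample_rate, tr$sample_rate, tolerance = 1e-9)
  expect_equal(back$meta$participant, "P01")
})

test_that("low-pass filter has unit DC gain and rejects bad parameters", {
  tr <- force_trace(rep(500, 3000))
  out <- lowpass_filter(tr)
  expect_lt(max(abs(out$force - 500)), 1e-6)
  expect_length(out$force, 3000)

  expect_error(lowpass_filter(tr, cutoff = 500), "Nyquist")
  expect_error(lowpass_filter(force_trace(rep(1, 100))), "too short")
})

test_that("filter steady-state gain matches the analytic Butterworth cascade", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  for (f in c(2, 10, 50)) {
    tr <- force_trace(100 * sin(2 * pi * f * t), fs)
    filt <- lowpass_filter(tr, cutoff = 10)
    # measure amplitude mid-trace, away from any residual edge effects
    amp <- max(abs(filt$force[2001:3000]))
    expected <- 100 * butterworth_cascade_gain(f, 10, fs)
    expect_equal(amp, expected, tolerance = 0.05)
  }
  # at the cutoff the cascaded fourth-order magnitude is exactly 1/2
  expect_equal(butterworth_cascade_gain(10, 10, fs), 0.5, tolerance = 1e-12)
})

test_that("filtering is zero-phase: symmetric pulses keep their extremum", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)
  tri <- force_trace(800 * pmax(0, 1 - abs(t - 1.5) / 0.4), fs)
  filt <- lowpass_filter(tri)
  expect_lte(abs(which.max(filt$force) - which.max(tri$force)), 1)
  # cross-correlation lag between input and output is zero
  cc <- stats::ccf(tri$force, filt$force, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("onset detection matches analytic crossings and the scan oracle", {
  fs <- 1000
  ramp <- force_trace(1000 * seq(0, 1, by = 1 / fs), fs)
  expect_equal(detect_onset(ramp, baseline_ms = 0), 0.010)

  step <- force_trace(c(rep(0, 500), rep(800, 1500)), fs)
  expect_equal(detect_onset(step, baseline_ms = 0), 0.500)

  # noisy logistic rise: forward-scan oracle on the same corrected signal
  for (seed in 1:5) {
    set.seed(seed)
    tt <- seq(0, 3, by = 1 / fs)
    f <- 900 / (1 + exp(-12 * (tt - 1.5))) + rnorm(length(tt), 0, 2)
    f <- f - mean(f[1:200])
    tr <- force_trace(f, fs)
    expect_equal(
      detect_onset(tr, baseline_ms = 0),
      brute_onset(f, fs)
    )
  }

  expect_error(detect_onset(force_trace(rep(0, 1000)), baseline_ms = 0),
    "no onset"
  )
  flat <- force_trace(c(0, rep(1000, 10), rep(0, 989)))
  expect_error(
    detect_onset(flat, sustain_ms = 50, baseline_ms = 0),
    "never sustained"
  )
})

test_that("peak force epoch equals the brute-force window oracle", {
  fs <- 1000
  expect_equal(peak_force_epoch(force_trace(rep(600, 2000)), 500), 600)

  plateau <- force_trace(c(rep(0, 1000), rep(1000, 1000), rep(0, 1000)), fs)
  expect_equal(peak_force_epoch(plateau, 500), 1000)

  t <- seq(0, 3, by = 1 / fs)
  tri <- force_trace(pmax(0, 1000 - 2000 * abs(t - 1.5)), fs)
  expect_equal(peak_force_epoch(tri, 500), 750, tolerance = 1e-3)

  for (seed in 1:20) {
    tr <- random_trace(seed)
    expect_equal(
      peak_force_epoch(tr, 500),
      brute_peak_epoch(tr$force, tr$sample_rate, 500)
    )
  }
  expect_error(peak_force_epoch(force_trace(rep(1, 100)), 500), "shorter")
})

test_that("windowed RFD is exact on ramps and closed-form on parabolas", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  ramp <- force_trace(1500 * t, fs)
  for (w in c(50, 100, 200)) {
    expect_equal(rfd_window(ramp, 0, w), 1500)
  }
  quad <- force_trace(40000 * t^2, fs)
  expect_equal(rfd_window(quad, 0, 50), 2000)
  expect_equal(rfd_window(quad, 0, 200), 8000)
  expect_equal(rfd_window(force_trace(rep(300, 1000), fs), 0, 50), 0)
  expect_error(rfd_window(ramp, 0.9, 200), "past the trace end")
})

test_that("peak RFD finds the steepest window and matches the scan oracle", {
  fs <- 1000
  t <- seq(0, 1, by = 1 / fs)
  ramp <- force_trace(1500 * t, fs)
  expect_equal(rfd_peak(ramp, 0), 1500, tolerance = 1e-9)

  # piecewise ramp: 1000 N/s for 100 ms then 3000 N/s for 100 ms
  pw <- force_trace(
    c(1000 * seq(0, 0.1, by = 1 / fs),
      100 + 3000 * seq(1 / fs, 0.1, by = 1 / fs),
      rep(400, 500)),
    fs
  )
  expect_equal(rfd_peak(pw, 0), 3000, tolerance = 0.02)
  expect_equal(
    rfd_peak(pw, 0),
    brute_rfd_peak(pw$force, fs, 1, 20)
  )
  # least-squares slope agrees on smooth ramps
  expect_equal(rfd_peak(ramp, 0, method = "least_squares"), 1500,
    tolerance = 1e-9
  )
  expect_equal(rfd_peak(force_trace(rep(250, 500), fs), 0), 0)
})

test_that("isometric metrics scale linearly with force (relative onset)", {
  sim <- simulate_isometric_trace(simulation_config(
    seed = 11, trace = list(noise_sd = 0, baseline_n = 0)
  ))
  m1 <- isometric_metrics(sim$trace, baseline_ms = 0)
  k <- 2.5
  scaled <- sim$trace
  scaled$force <- k * scaled$force
  m2 <- isometric_metrics(scaled, baseline_ms = 0)
  expect_equal(m2$pf_iso, k * m1$pf_iso, tolerance = 1e-9)
  expect_equal(m2$rfd50, k * m1$rfd50, tolerance = 1e-9)
  expect_equal(m2$rfd200, k * m1$rfd200, tolerance = 1e-9)
  expect_equal(m2$rfd_peak, k * m1$rfd_peak, tolerance = 1e-9)
  expect_equal(m2$onset_time, m1$onset_time)
  expect_lte(m1$pf_iso, m1$max_force + 1e-9)
})
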