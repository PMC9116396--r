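test_that("simulation is fully deterministic given the config", {
  cfg <- simulation_config(seed = 12)
  a <- simulate_crossover_trial(cfg)
  b <- simulate_crossover_trial(cfg)
  expect_identical(a, b)

  t1 <- simulate_isometric_trace(cfg)
  t2 <- simulate_isometric_trace(cfg)
  expect_identical(t1$trace$force, t2$trace$force)

  k1 <- simulate_isokinetic_trace(cfg)
  k2 <- simulate_isokinetic_trace(cfg)
  expect_identical(k1$trace$force, k2$trace$force)
})

test_that("noise-free isometric traces reproduce their analytic truths", {
  cfg <- simulation_config(seed = 5, trace = list(noise_sd = 0))
  sim <- simulate_isometric_trace(cfg)
  m <- isometric_metrics(sim$trace)
  expect_equal(m$pf_iso, sim$truth$pf_iso, tolerance = 0.001)
  expect_equal(m$rfd50, sim$truth$rfd50, tolerance = 0.01)
  expect_equal(m$rfd200, sim$truth$rfd200, tolerance = 0.01)
  expect_equal(m$rfd_peak, sim$truth$rfd_peak, tolerance = 0.01)
  expect_equal(m$onset_time, sim$truth$onset_time, tolerance = 0.005)

  expect_error(
    simulate_isometric_trace(cfg, true_rfd_slope = 300),
    "rise incompatible"
  )

  # linear rise mode: every RFD truth is exactly the commanded slope
  lin <- simulate_isometric_trace(cfg, rise = "linear")
  expect_equal(lin$truth$rfd50, cfg$trace$rfd_slope)
  expect_equal(lin$truth$rfd_peak, cfg$trace$rfd_slope)
  onset <- detect_onset(lin$trace)
  expect_equal(onset, lin$truth$onset_time, tolerance = 0.01)
  expect_equal(rfd_window(lin$trace, onset, 200), cfg$trace$rfd_slope,
    tolerance = 0.01
  )
})

test_that("noisy isometric peak force is recovered without bias", {
  cfg <- simulation_config(trace = list(noise_sd = 5))
  rel_err <- vapply(1:200, function(seed) {
    sim <- simulate_isometric_trace(cfg, seed = seed)
    m <- isometric_metrics(sim$trace)
    (m$pf_iso - sim$truth$pf_iso) / sim$truth$pf_iso
  }, numeric(1))
  expect_lt(abs(mean(rel_err)), 0.005)
})

test_that("isokinetic traces encode the commanded per-rep plateau peaks", {
  cfg0 <- simulation_config(seed = 8, trace = list(noise_sd = 0))
  pk <- data.frame(ecc = c(600, 600, 600), con = c(800, 800, 800))
  sim <- simulate_isokinetic_trace(cfg0, per_rep_peaks = pk)
  phases <- segment_isokinetic(sim$trace, sim$timeline)
  mets <- isokinetic_peaks(sim$trace, phases)
  expect_equal(mets$pf_con, 800, tolerance = 1e-9)
  expect_equal(mets$pf_ecc, 600, tolerance = 1e-9)

  pk2 <- data.frame(ecc = c(500, 550, 560), con = c(700, 800, 900))
  sim2 <- simulate_isokinetic_trace(cfg0, per_rep_peaks = pk2)
  mets2 <- isokinetic_peaks(sim2$trace, segment_isokinetic(sim2$trace, sim2$timeline))
  expect_equal(mets2$pf_con, 850) # mean of the analysed reps 2 and 3
  expect_equal(mets2$per_rep$pf_con, c(800, 900))

  expect_error(
    simulate_isokinetic_trace(cfg0, per_rep_peaks = data.frame(
      ecc = c(-1, 1, 1), con = c(1, 1, 1)
    )),
    "non-negative"
  )

  # timeline structure: 3 reps x phases, non-overlapping, quoted durations
  tl <- phase_timeline(n_reps = 3, rep_start = 0)
  r1 <- tl[tl$rep_index == 1, ]
  expect_equal(
    r1$start[r1$label %in% c("eccentric", "pause_bottom", "concentric")],
    c(0, 4, 5)
  )
  expect_equal(
    r1$end[r1$label %in% c("eccentric", "pause_bottom", "concentric")],
    c(4, 5, 9)
  )
  expect_equal(nrow(tl[tl$label != "pause_top", ]), 9)
  by_rep <- split(tl, tl$rep_index)
  for (rr in by_rep) {
    o <- rr[order(rr$start), ]
    expect_true(all(o$end[-nrow(o)] <= o$start[-1] + 1e-12))
  }

  # truncated mid-rep-3 trace names the offending rep
  short <- force_trace(rep(100, 20000)) # 20 s < rep 3 concentric end
  expect_error(segment_isokinetic(short, phase_timeline()), "rep 3")
})

test_that("noisy isokinetic per-rep peaks match the brute-force oracle", {
  cfg <- simulation_config(trace = list(noise_sd = 4))
  for (seed in 1:10) {
    sim <- simulate_isokinetic_trace(cfg, seed = seed)
    filt <- lowpass_filter(sim$trace)
    phases <- segment_isokinetic(filt, sim$timeline)
    mets <- isokinetic_peaks(filt, phases)
    for (r in 2:3) {
      for (lab in c("concentric", "eccentric")) {
        ph <- phases[phases$rep_index == r & phases$label == lab, ]
        i0 <- round((ph$start - filt$t0) * filt$sample_rate) + 1
        i1 <- round((ph$end - filt$t0) * filt$sample_rate) + 1
        oracle <- brute_peak_epoch(filt$force[i0:i1], filt$sample_rate, 25)
        got <- mets$per_rep[[if (lab == "concentric") "pf_con" else "pf_ecc"]][
          mets$per_rep$rep_index == r
        ]
        expect_equal(got, oracle)
      }
    }
  }
})

test_that("crossover tables carry the design dimensions and injected truth", {
  cfg <- simulation_config(seed = 3)
  sim <- simulate_crossover_trial(cfg)
  d <- sim$data
  one_single <- d[d$outcome == "pf_iso", ]
  expect_equal(nrow(one_single), 24 * 3)
  one_vas <- d[d$outcome == "energy", ]
  expect_equal(nrow(one_vas), 24 * 3 * 5)
  expect_equal(sort(unique(one_vas$timepoint)), 1:5)
  expect_true(all(d$value[d$kind == "repeated"] >= 0 &
    d$value[d$kind == "repeated"] <= 100))
  expect_lt(sim$truth$vas_clamp_rate, 0.2)

  # all effects and noise zero: every outcome equals the grand mean
  flat <- simulation_config(
    seed = 1,
    single_outcomes = list(y = single_outcome_params(42,
      sd_participant = 0, sd_residual = 0
    )),
    vas_outcomes = list(), missing_rate = 0
  )
  expect_true(all(simulate_crossover_trial(flat)$data$value == 42))
})

test_that("missingness injection hits the binomial expectation", {
  d <- simulate_crossover_trial(simulation_config(
    seed = 2, single_outcomes = list(),
    vas_outcomes = list(energy = vas_outcome_params(50))
  ))$data
  expect_equal(nrow(d), 360)

  expect_identical(inject_missingness(d, rate = 0, seed = 1), d)
  expect_error(inject_missingness(d, rate = 0.5, seed = 1), "0.5")
  expect_error(inject_missingness(d, rate = -0.1, seed = 1), "0.5")

  counts <- vapply(1:1000, function(s) {
    sum(is.na(inject_missingness(d, rate = 0.033, seed = s)$value))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 360 * 0.033), 1)
  # single-value outcomes stay untouched
  mixed <- simulate_crossover_trial(simulation_config(seed = 4))$data
  dm <- inject_missingness(mixed, rate = 0.2, seed = 3)
  expect_false(anyNA(dm$value[dm$kind == "single"]))
  expect_gt(sum(is.na(dm$value[dm$kind == "repeated"])), 0)
})
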