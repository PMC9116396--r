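# Independent brute-force oracles used across the signal tests.

# O(n * w) scan over every contiguous window: maximal windowed mean
brute_peak_epoch <- function(force, sample_rate, window_ms) {
  w <- round(window_ms / 1000 * sample_rate)
  stopifnot(length(force) >= w)
  max(vapply(seq_len(length(force) - w + 1), function(i) {
    mean(force[i:(i + w - 1)])
  }, numeric(1)))
}

# exhaustive forward scan for the first sustained threshold crossing
brute_onset <- function(force, sample_rate, threshold_fraction = 0.01,
                        sustain_ms = 10) {
  thr <- threshold_fraction * max(force)
  sustain_n <- max(1L, round(sustain_ms / 1000 * sample_rate))
  for (i in seq_len(length(force) - sustain_n + 1)) {
    if (all(force[i:(i + sustain_n - 1)] >= thr)) {
      return((i - 1) / sample_rate)
    }
  }
  NA_real_
}

# exhaustive windowed endpoint-slope scan between onset and force maximum
brute_rfd_peak <- function(force, sample_rate, onset_idx, w) {
  i_max <- which.max(force)
  last <- max(onset_idx, i_max - w)
  max(vapply(onset_idx:last, function(i) {
    (force[i + w] - force[i]) / (w / sample_rate)
  }, numeric(1)))
}

# random smooth-ish positive trace for window-scan equivalence checks
random_trace <- function(seed, n = 1200, sample_rate = 1000) {
  set.seed(seed)
  base <- cumsum(stats::rnorm(n, 0, 4))
  force_trace(base - min(base) + stats::runif(1, 0, 50) +
    stats::rnorm(n, 0, 2), sample_rate)
}

# hand-built truth table: carryover coding for all 6 sequences x 3 visits.
# x1 flags a preceding caffeinated condition, x2 a preceding non-caffeinated
# one; first-period and placebo-preceded rows are (0, 0).
carryover_truth_table <- function() {
  rows <- list(
    list("C-NC-P", 1, 0L, 0L), list("C-NC-P", 2, 1L, 0L), list("C-NC-P", 3, 0L, 1L),
    list("C-P-NC", 1, 0L, 0L), list("C-P-NC", 2, 1L, 0L), list("C-P-NC", 3, 0L, 0L),
    list("NC-C-P", 1, 0L, 0L), list("NC-C-P", 2, 0L, 1L), list("NC-C-P", 3, 1L, 0L),
    list("NC-P-C", 1, 0L, 0L), list("NC-P-C", 2, 0L, 1L), list("NC-P-C", 3, 0L, 0L),
    list("P-C-NC", 1, 0L, 0L), list("P-C-NC", 2, 0L, 0L), list("P-C-NC", 3, 1L, 0L),
    list("P-NC-C", 1, 0L, 0L), list("P-NC-C", 2, 0L, 0L), list("P-NC-C", 3, 0L, 1L)
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      sequence = r[[1]], visit = r[[2]], x1 = r[[3]], x2 = r[[4]],
      stringsAsFactors = FALSE
    )
  }))
}

# small simulation configs for the model tests: a single outcome with the
# stated effect/noise structure, nothing else
one_outcome_config <- function(seed, effect_c = 5, effect_nc = 0,
                               sd_participant = 8, sd_residual = 6,
                               n_per_sex = 12, grand = 50) {
  simulation_config(
    seed = seed, n_per_sex = n_per_sex,
    single_outcomes = list(y = single_outcome_params(
      grand,
      c_effect = effect_c, nc_effect = effect_nc,
      sd_participant = sd_participant, sd_residual = sd_residual
    )),
    vas_outcomes = list(), missing_rate = 0
  )
}

one_vas_config <- function(seed, phi = 0.6, c_effect = 5,
                           sd_participant = 10, sd_residual = 8,
                           n_per_sex = 12) {
  simulation_config(
    seed = seed, n_per_sex = n_per_sex,
    single_outcomes = list(),
    vas_outcomes = list(energy = vas_outcome_params(
      50,
      c_effect = c_effect, phi = phi,
      sd_participant = sd_participant, sd_residual = sd_residual,
      time_profile = c(0, 4, 3, 1, -1), c_time = 0, nc_time = 0
    )),
    missing_rate = 0
  )
}
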