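#' Simulation configuration
#'
#' Ground-truth parameters, noise and missingness settings, and the seed for
#' the synthetic-data generators. The defaults emulate the trial design:
#' 24 participants (12 per sex) across six counterbalanced sequences, 1-kHz
#' load-cell traces, five visual-analog-scale timepoints with AR1(0.6)
#' within-series residual correlation, and 3.3% missingness in the
#' visual-analog-scale records.
#'
#' @param seed Integer master seed.
#' @param n_per_sex Participants per sex (default 12; must be divisible by 6).
#' @param trace Named list of trace parameters: `baseline_n` (resting preload,
#'   N), `pf_n` (plateau force above baseline, N), `rfd_slope` (maximal rise
#'   slope, N/s), `noise_sd` (N), `duration_s`, `baseline_dur_s`,
#'   `sample_rate` (Hz), `rest_n` (between-phase force for isokinetic traces).
#' @param single_outcomes Named list of single-value outcome parameter lists
#'   (see [single_outcome_params()]); defaults cover the six squat and four
#'   resistance-exercise outcomes.
#' @param vas_outcomes Named list of repeated-outcome parameter lists (see
#'   [vas_outcome_params()]); defaults cover energy, focus and fatigue.
#' @param missing_rate Per-cell missingness probability for
#'   visual-analog-scale records (default 0.033).
#' @param transform_presets Named character vector mapping outcomes to their
#'   preset analysis transforms (`log_x` for `pf_iso` and `rfd50`,
#'   `ordered_quantile` for `rfd_peak`).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_per_sex = 12,
                              trace = list(),
                              single_outcomes = default_single_outcomes(),
                              vas_outcomes = default_vas_outcomes(),
                              missing_rate = 0.033,
                              transform_presets = c(
                                pf_iso = "log_x", rfd50 = "log_x",
                                rfd_peak = "ordered_quantile"
                              )) {
  tr <- utils::modifyList(list(
    baseline_n = 800, pf_n = 2000, rfd_slope = 8000, noise_sd = 5,
    duration_s = 4, baseline_dur_s = 0.75, sample_rate = 1000, rest_n = 150
  ), trace)
  if (n_per_sex %% 6 != 0) {
    stop("n_per_sex must be divisible by 6", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 0.5) {
    stop("missing_rate must lie in [0, 0.5)", call. = FALSE)
  }
  stopifnot(tr$sample_rate > 0, tr$noise_sd >= 0)
  for (oc in c(single_outcomes, vas_outcomes)) {
    stopifnot(oc$sd_participant >= 0, oc$sd_residual >= 0)
    if (!is.null(oc$phi) && abs(oc$phi) >= 1) {
      stop("|phi| must be < 1", call. = FALSE)
    }
  }
  structure(
    list(
      seed = seed, n_per_sex = n_per_sex, trace = tr,
      single_outcomes = single_outcomes, vas_outcomes = vas_outcomes,
      missing_rate = missing_rate, transform_presets = transform_presets
    ),
    class = "simulation_config"
  )
}

#' Outcome parameter sets for the trial simulator
#'
#' `single_outcome_params()` parameterises one single-value outcome (one row
#' per participant x condition): grand mean, additive effects of the
#' caffeinated (`c_effect`) and non-caffeinated (`nc_effect`) conditions
#' versus placebo, a male-vs-female effect, condition x sex interactions,
#' period (visit 2/3) effects, carryover effects for the two coded variables,
#' and participant-intercept / residual standard deviations, all in the
#' outcome's units. `vas_outcome_params()` adds the repeated-measures pieces:
#' a five-timepoint profile (deltas versus the pre-ingestion baseline), extra
#' post-baseline condition effects (the condition x time signal), and the AR1
#' coefficient of the within-series residuals.
#'
#' @param grand_mean,c_effect,nc_effect,sex_effect Fixed-effect truths.
#' @param c_sex,nc_sex Condition x sex interaction truths.
#' @param visit2,visit3 Period-effect truths.
#' @param x1_effect,x2_effect Carryover-effect truths (preceding C / NC).
#' @param sd_participant,sd_residual Random-intercept and residual SDs.
#' @return A named list of truth parameters.
#' @export
single_outcome_params <- function(grand_mean, c_effect = 0, nc_effect = 0,
                                  sex_effect = 0, c_sex = 0, nc_sex = 0,
                                  visit2 = 0, visit3 = 0,
                                  x1_effect = 0, x2_effect = 0,
                                  sd_participant = 1, sd_residual = 1) {
  list(
    kind = "single", grand_mean = grand_mean, c_effect = c_effect,
    nc_effect = nc_effect, sex_effect = sex_effect, c_sex = c_sex,
    nc_sex = nc_sex, visit2 = visit2, visit3 = visit3,
    x1_effect = x1_effect, x2_effect = x2_effect,
    sd_participant = sd_participant, sd_residual = sd_residual
  )
}

#' @rdname single_outcome_params
#' @param time_profile Length-5 numeric: timepoint means relative to
#'   timepoint 1.
#' @param c_time,nc_time Additional condition effect at timepoints 2-5
#'   (condition x time truth).
#' @param phi AR1 coefficient of within participant x condition residuals.
#' @export
vas_outcome_params <- function(grand_mean = 50, c_effect = 0, nc_effect = 0,
                               sex_effect = 0, c_sex = 0, nc_sex = 0,
                               visit2 = 0, visit3 = 0,
                               x1_effect = 0, x2_effect = 0,
                               time_profile = c(0, 8, 5, 2, -2),
                               c_time = 0, nc_time = 0, phi = 0.6,
                               sd_participant = 10, sd_residual = 8) {
  out <- single_outcome_params(
    grand_mean, c_effect, nc_effect, sex_effect, c_sex, nc_sex,
    visit2, visit3, x1_effect, x2_effect, sd_participant, sd_residual
  )
  out$kind <- "repeated"
  stopifnot(length(time_profile) == 5)
  out$time_profile <- time_profile
  out$c_time <- c_time
  out$nc_time <- nc_time
  out$phi <- phi
  out
}

#' @rdname single_outcome_params
#' @export
default_single_outcomes <- function() {
  list(
    pf_iso = single_outcome_params(2500, 100, 60, 1300,
      visit2 = 15, visit3 = 25, sd_participant = 450, sd_residual = 120
    ),
    rfd50 = single_outcome_params(4500, 250, 150, 1800,
      sd_participant = 1400, sd_residual = 500
    ),
    rfd200 = single_outcome_params(5200, 220, 130, 2000,
      sd_participant = 1500, sd_residual = 450
    ),
    rfd_peak = single_outcome_params(9000, 350, 200, 3500,
      sd_participant = 2600, sd_residual = 700
    ),
    pf_con = single_outcome_params(1700, 45, 30, 800,
      sd_participant = 320, sd_residual = 80
    ),
    pf_ecc = single_outcome_params(1900, 40, 25, 900,
      sd_participant = 350, sd_residual = 90
    ),
    bp_1rm = single_outcome_params(70, 1.5, 1, 45,
      sd_participant = 12, sd_residual = 2
    ),
    bp_rtf = single_outcome_params(12, 1, 0.7, 2,
      sd_participant = 4, sd_residual = 1.5
    ),
    lp_1rm = single_outcome_params(220, 5, 3, 90,
      sd_participant = 45, sd_residual = 7
    ),
    lp_rtf = single_outcome_params(18, 1.5, 1, 3,
      sd_participant = 6, sd_residual = 2.5
    )
  )
}

#' @rdname single_outcome_params
#' @export
default_vas_outcomes <- function() {
  list(
    energy = vas_outcome_params(50, 4, 2.5, 0,
      time_profile = c(0, 10, 7, 3, -3), c_time = 6, nc_time = 3
    ),
    focus = vas_outcome_params(55, 3, 2, 0,
      time_profile = c(0, 8, 6, 3, -1), c_time = 5, nc_time = 2.5
    ),
    fatigue = vas_outcome_params(35, -3, -2, 0,
      time_profile = c(0, -5, 0, 6, 12), c_time = -4, nc_time = -2
    )
  )
}

# logistic latent force curve (above baseline): amplitude A, max slope at tm
logistic_force <- function(t, A, k, tm) {
  A / (1 + exp(-k * (t - tm)))
}

#' Simulate an isometric maximal-push force trace
#'
#' Generates a 1-kHz load-cell trace for one maximal isometric push: a
#' bodyweight-preload baseline segment, a smooth logistic rise of amplitude
#' `true_pf` whose maximal slope is `true_rfd_slope`, a plateau, and seeded
#' additive Gaussian noise. The logistic shape makes every target metric
#' analytic; the returned truth record stores closed-form values for the
#' noise-free latent curve (peak 500-ms epoch mean, onset at the 1% relative
#' threshold, 50/200-ms and peak windowed rates of force development).
#'
#' @param config A [simulation_config()] supplying trace defaults.
#' @param true_pf Plateau force above baseline, N (default from config).
#' @param true_rfd_slope Maximal rise slope, N/s (default from config).
#' @param seed Integer seed for the noise (default `config$seed`).
#' @param epoch_ms,rfd_windows_ms,slope_window_ms Analysis windows mirrored
#'   into the truth record (defaults 500, c(50, 200), 20).
#' @param rise `"logistic"` (smooth, differentiable, default) or `"linear"`
#'   (exact constant slope from baseline to plateau, for exact-slope checks).
#' @return List with `trace` (a [force_trace()]) and `truth` (named list:
#'   `pf_iso`, `onset_time`, `rfd50`, `rfd200`, `rfd_peak`, plus the inputs).
#' @export
simulate_isometric_trace <- function(config = simulation_config(),
                                     true_pf = config$trace$pf_n,
                                     true_rfd_slope = config$trace$rfd_slope,
                                     seed = config$seed,
                                     epoch_ms = 500,
                                     rfd_windows_ms = c(50, 200),
                                     slope_window_ms = 20,
                                     rise = c("logistic", "linear")) {
  tr <- config$trace
  rise <- match.arg(rise)
  if (true_pf <= 0) stop("true_pf must exceed the baseline", call. = FALSE)
  A <- true_pf
  if (rise == "linear") {
    t_rise <- A / true_rfd_slope
    t_start <- tr$baseline_dur_s
    if (t_start + t_rise + epoch_ms / 1000 > tr$duration_s) {
      stop(sprintf(
        "rise incompatible with duration: plateau starts at %.2f s but the trace ends at %.2f s",
        t_start + t_rise, tr$duration_s
      ), call. = FALSE)
    }
    n <- round(tr$duration_s * tr$sample_rate) + 1
    t <- (seq_len(n) - 1) / tr$sample_rate
    latent <- tr$baseline_n + pmin(A, pmax(0, (t - t_start) * true_rfd_slope))
    set.seed(seed)
    trace <- force_trace(latent + stats::rnorm(n, 0, tr$noise_sd),
      sample_rate = tr$sample_rate,
      meta = list(trial_kind = "isometric")
    )
    truth <- list(
      true_pf = true_pf, true_rfd_slope = true_rfd_slope,
      baseline = tr$baseline_n, rise = "linear",
      pf_iso = A,
      onset_time = t_start + 0.01 * A / true_rfd_slope,
      rfd50 = true_rfd_slope, rfd200 = true_rfd_slope,
      rfd_peak = true_rfd_slope
    )
    return(list(trace = trace, truth = truth))
  }
  k <- 4 * true_rfd_slope / A
  # rise is 99.9% complete ln(999)/k after the midpoint; centre the midpoint
  # so the signal is still < 0.1% of A at the end of the baseline window
  lead <- log(999) / k
  tm <- tr$baseline_dur_s + lead
  t_plateau <- tm + lead
  if (t_plateau + epoch_ms / 1000 > tr$duration_s) {
    stop(sprintf(
      "rise incompatible with duration: plateau starts at %.2f s but the trace ends at %.2f s",
      t_plateau, tr$duration_s
    ), call. = FALSE)
  }
  n <- round(tr$duration_s * tr$sample_rate) + 1
  t <- (seq_len(n) - 1) / tr$sample_rate
  latent <- tr$baseline_n + logistic_force(t, A, k, tm)
  set.seed(seed)
  noise <- stats::rnorm(n, 0, tr$noise_sd)
  trace <- force_trace(latent + noise,
    sample_rate = tr$sample_rate,
    meta = list(trial_kind = "isometric")
  )
  # analytic truths on the latent (baseline-corrected) curve
  t_end <- tr$duration_s
  w <- epoch_ms / 1000
  int_logistic <- function(a, b) {
    # integral of A / (1 + exp(-k (t - tm))) over [a, b]
    (A / k) * (log1p(exp(k * (b - tm))) - log1p(exp(k * (a - tm))))
  }
  onset <- tm - log(99) / k
  fval <- function(tt) logistic_force(tt, A, k, tm)
  sw <- slope_window_ms / 1000
  truth <- list(
    true_pf = true_pf, true_rfd_slope = true_rfd_slope,
    baseline = tr$baseline_n, k = k, midpoint = tm,
    pf_iso = int_logistic(t_end - w, t_end) / w,
    onset_time = onset,
    rfd50 = (fval(onset + 0.05) - fval(onset)) / 0.05,
    rfd200 = (fval(onset + 0.2) - fval(onset)) / 0.2,
    rfd_peak = A * tanh(k * sw / 4) / sw
  )
  list(trace = trace, truth = truth)
}

#' Simulate an isokinetic squat-set force trace
#'
#' Generates a phase-structured trace for one 3-repetition machine-paced
#' squat set: each repetition is a 4-s eccentric phase, ~1-s bottom pause and
#' 4-s concentric phase (1-s top pause between reps), with trapezoidal force
#' plateaus at the supplied per-repetition peak targets plus seeded Gaussian
#' noise. The plateau values are the known per-phase 25-ms-epoch maxima.
#'
#' @param config A [simulation_config()].
#' @param per_rep_peaks Data.frame (or list of 3 pairs) with columns
#'   `ecc` and `con`: target peak force per repetition, N.
#' @param seed Integer seed for the noise.
#' @param ramp_s Rise/fall time of each trapezoid edge (default 0.5 s).
#' @return List with `trace`, `timeline` (the [phase_timeline()]) and
#'   `truth` (data.frame `rep_index`, `pf_ecc`, `pf_con`).
#' @export
simulate_isokinetic_trace <- function(config = simulation_config(),
                                      per_rep_peaks = data.frame(
                                        ecc = c(600, 620, 640),
                                        con = c(800, 820, 840)
                                      ),
                                      seed = config$seed,
                                      ramp_s = 0.5) {
  tr <- config$trace
  pk <- as.data.frame(per_rep_peaks)
  if (nrow(pk) != 3L || !all(c("ecc", "con") %in% names(pk))) {
    stop("per_rep_peaks must give ecc and con targets for 3 reps", call. = FALSE)
  }
  if (any(pk$ecc < 0 | pk$con < 0)) {
    stop("per-rep peak targets must be non-negative", call. = FALSE)
  }
  timeline <- phase_timeline(n_reps = 3, rep_start = 1)
  dur <- max(timeline$end) + 0.5
  n <- round(dur * tr$sample_rate) + 1
  t <- (seq_len(n) - 1) / tr$sample_rate
  f <- rep(tr$rest_n, n)
  trapezoid <- function(tt, start, end, peak) {
    up <- pmin(1, pmax(0, (tt - start) / ramp_s))
    down <- pmin(1, pmax(0, (end - tt) / ramp_s))
    tr$rest_n + (peak - tr$rest_n) * pmin(up, down)
  }
  for (r in 1:3) {
    for (lab in c("eccentric", "concentric")) {
      ph <- timeline[timeline$rep_index == r & timeline$label == lab, ]
      sel <- t >= ph$start & t <= ph$end
      peak <- if (lab == "eccentric") pk$ecc[r] else pk$con[r]
      f[sel] <- trapezoid(t[sel], ph$start, ph$end, peak)
    }
  }
  set.seed(seed)
  f <- f + stats::rnorm(n, 0, tr$noise_sd)
  list(
    trace = force_trace(f,
      sample_rate = tr$sample_rate,
      meta = list(trial_kind = "isokinetic")
    ),
    timeline = timeline,
    truth = data.frame(rep_index = 1:3, pf_ecc = pk$ecc, pf_con = pk$con)
  )
}

#' Simulate a complete crossover trial table
#'
#' Draws a counterbalanced assignment, expands it to per-visit records with
#' carryover coding, and generates every configured outcome: single-value
#' outcomes as grand mean + injected fixed effects + participant intercept +
#' residual; visual-analog-scale outcomes additionally carry a five-timepoint
#' profile, condition x time effects, and stationary AR1 residual series
#' within each participant x condition. Values are generated on the latent
#' continuous scale; visual-analog-scale scores are clamped to [0, 100] and
#' the clamping rate is reported in the truth record.
#'
#' @param config A [simulation_config()].
#' @return List with `data` (long trial table: `participant_id`, `sex`,
#'   `sequence`, `visit`, `condition`, `preceding_condition`, `x1`, `x2`,
#'   `outcome`, `kind`, `timepoint`, `value`) and `truth` (every injected
#'   parameter plus `vas_clamp_rate`).
#' @export
simulate_crossover_trial <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  assign <- generate_counterbalanced_assignment(config$n_per_sex, config$seed)
  records <- code_carryover(assignment_records(assign))
  set.seed(config$seed + 1L)
  fixed_mean <- function(oc, rec, tp = NULL) {
    mu <- oc$grand_mean +
      ifelse(rec$condition == "C", oc$c_effect,
        ifelse(rec$condition == "NC", oc$nc_effect, 0)
      ) +
      ifelse(rec$sex == "male", oc$sex_effect, 0) +
      ifelse(rec$condition == "C" & rec$sex == "male", oc$c_sex, 0) +
      ifelse(rec$condition == "NC" & rec$sex == "male", oc$nc_sex, 0) +
      ifelse(rec$visit == 2, oc$visit2, ifelse(rec$visit == 3, oc$visit3, 0)) +
      rec$x1 * oc$x1_effect + rec$x2 * oc$x2_effect
    if (!is.null(tp)) {
      mu <- mu + oc$time_profile[tp] +
        ifelse(rec$condition == "C" & tp > 1, oc$c_time,
          ifelse(rec$condition == "NC" & tp > 1, oc$nc_time, 0)
        )
    }
    mu
  }
  parts <- unique(records$participant_id)
  out <- list()
  clamped <- 0L
  vas_cells <- 0L
  for (nm in names(config$single_outcomes)) {
    oc <- config$single_outcomes[[nm]]
    b <- stats::setNames(stats::rnorm(length(parts), 0, oc$sd_participant), parts)
    rows <- records
    rows$outcome <- nm
    rows$kind <- "single"
    rows$timepoint <- NA_integer_
    rows$value <- fixed_mean(oc, records) + b[records$participant_id] +
      stats::rnorm(nrow(records), 0, oc$sd_residual)
    out[[nm]] <- rows
  }
  for (nm in names(config$vas_outcomes)) {
    oc <- config$vas_outcomes[[nm]]
    b <- stats::setNames(stats::rnorm(length(parts), 0, oc$sd_participant), parts)
    rows <- records[rep(seq_len(nrow(records)), each = 5), ]
    rows$timepoint <- rep(1:5, times = nrow(records))
    rows$outcome <- nm
    rows$kind <- "repeated"
    # stationary AR1 residual series per participant x condition
    eps <- as.numeric(vapply(seq_len(nrow(records)), function(i) {
      e <- numeric(5)
      e[1] <- stats::rnorm(1, 0, oc$sd_residual)
      for (tt in 2:5) {
        e[tt] <- oc$phi * e[tt - 1] +
          stats::rnorm(1, 0, oc$sd_residual * sqrt(1 - oc$phi^2))
      }
      e
    }, numeric(5)))
    latent <- fixed_mean(oc, rows, tp = rows$timepoint) +
      b[rows$participant_id] + eps
    value <- pmin(100, pmax(0, latent))
    clamped <- clamped + sum(value != latent)
    vas_cells <- vas_cells + length(value)
    rows$value <- value
    out[[nm]] <- rows
  }
  data <- do.call(rbind, out)
  rownames(data) <- NULL
  truth <- list(
    config = config,
    assignment = assign,
    outcomes = c(config$single_outcomes, config$vas_outcomes),
    vas_clamp_rate = if (vas_cells > 0) clamped / vas_cells else 0
  )
  list(data = data, truth = truth)
}

#' Inject missing-completely-at-random cells
#'
#' Sets each eligible outcome cell to missing independently with probability
#' `rate`. By default only repeated (visual-analog-scale) records are
#' eligible, matching the trial's missingness pattern; single-value outcomes
#' are untouched.
#'
#' @param data Long trial table with `value` (and `kind`) columns.
#' @param rate Missingness probability in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param outcomes Optional character vector restricting eligibility to the
#'   named outcomes; default eligibility is `kind == "repeated"` rows.
#' @return The table with eligible values set to `NA` at the drawn cells.
#' @export
inject_missingness <- function(data, rate = 0.033, seed = 1, outcomes = NULL) {
  if (!is.numeric(rate) || rate < 0 || rate >= 0.5) {
    stop("rate must lie in [0, 0.5)", call. = FALSE)
  }
  eligible <- if (!is.null(outcomes)) {
    data$outcome %in% outcomes
  } else if ("kind" %in% names(data)) {
    data$kind == "repeated"
  } else {
    rep(TRUE, nrow(data))
  }
  if (rate == 0) {
    return(data)
  }
  set.seed(seed)
  drop <- eligible & stats::runif(nrow(data)) < rate
  data$value[drop] <- NA_real_
  data
}
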