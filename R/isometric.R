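#' Detect force onset by a relative sustained threshold
#'
#' Finds the initiation of force production as the first sample at or above
#' `threshold_fraction` of the maximal (baseline-corrected) force that stays
#' at or above the threshold for `sustain_ms` milliseconds. The default 1%
#' threshold is the automated-onset convention for instrumented strength
#' testing; the sustain window debounces single-sample noise crossings.
#'
#' Load cells read the bodyweight preload, so a relative threshold is only
#' meaningful on a zeroed signal: the baseline is taken as the mean of the
#' first `baseline_ms` of the trace and subtracted before thresholding. Pass
#' `baseline_ms = 0` for traces that are already baseline-corrected.
#'
#' @param trace A [force_trace()], normally low-pass filtered first.
#' @param threshold_fraction Fraction of the maximal corrected force defining
#'   onset (default 0.01, i.e. 1%).
#' @param sustain_ms Time (ms) the signal must remain at/above threshold for a
#'   crossing to count (default 10).
#' @param baseline_ms Length (ms) of the initial window whose mean force is
#'   treated as the zero level (default 200; 0 disables correction).
#'
#' @return Onset time in seconds (on the trace's clock).
#' @export
detect_onset <- function(trace, threshold_fraction = 0.01, sustain_ms = 10,
                         baseline_ms = 200) {
  stopifnot(inherits(trace, "force_trace"))
  corrected <- baseline_correct(trace, baseline_ms)$force
  fmax <- max(corrected)
  if (fmax <= 0) {
    stop("no onset: maximal baseline-corrected force is not positive",
      call. = FALSE
    )
  }
  thr <- threshold_fraction * fmax
  sustain_n <- max(1L, round(sustain_ms / 1000 * trace$sample_rate))
  above <- corrected >= thr
  # first index where `above` holds for sustain_n consecutive samples
  run <- stats::filter(as.numeric(above), rep(1, sustain_n),
    sides = 1
  )
  hit <- which(run == sustain_n)
  if (length(hit) == 0L) {
    stop(sprintf(
      "no onset: threshold %.3g N never sustained for %g ms", thr, sustain_ms
    ), call. = FALSE)
  }
  i_on <- hit[1] - sustain_n + 1L
  i_max <- which.max(corrected)
  if (i_on > i_max) {
    stop("no onset: first sustained crossing follows the force maximum",
      call. = FALSE
    )
  }
  trace$t0 + (i_on - 1) / trace$sample_rate
}

#' Baseline-correct a trace
#'
#' Subtracts the mean of the first `baseline_ms` of the trace (the resting
#' preload) from every sample. With `baseline_ms = 0` the trace is returned
#' unchanged.
#'
#' @param trace A [force_trace()].
#' @param baseline_ms Baseline window length in ms.
#' @return A [force_trace()] with corrected force.
#' @export
baseline_correct <- function(trace, baseline_ms = 200) {
  stopifnot(inherits(trace, "force_trace"))
  if (baseline_ms <= 0) {
    return(trace)
  }
  nb <- min(
    length(trace$force),
    max(1L, round(baseline_ms / 1000 * trace$sample_rate))
  )
  out <- trace
  out$force <- trace$force - mean(trace$force[seq_len(nb)])
  out
}

# moving mean of window w (samples), stride 1; returns n - w + 1 values
moving_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Highest mean-force epoch
#'
#' Scans every contiguous window of `window_ms` milliseconds (stride one
#' sample) and returns the maximal windowed mean force. With the default
#' 500-ms window this is the isometric peak-force definition used for
#' maximal-effort pushes.
#'
#' @param trace A [force_trace()] (filtered, and baseline-corrected if the
#'   preload should be excluded).
#' @param window_ms Epoch length in milliseconds (default 500).
#' @return Peak epoch mean force in newtons.
#' @export
peak_force_epoch <- function(trace, window_ms = 500) {
  stopifnot(inherits(trace, "force_trace"))
  w <- max(1L, round(window_ms / 1000 * trace$sample_rate))
  if (length(trace$force) < w) {
    stop(sprintf(
      "trace shorter than the %g ms epoch window (%d samples needed, %d available)",
      window_ms, w, length(trace$force)
    ), call. = FALSE)
  }
  max(moving_mean(trace$force, w))
}

#' Rate of force development over a fixed window from onset
#'
#' Difference quotient `(F(onset + window) - F(onset)) / window` on the
#' (filtered) force signal, in N/s. Windows of 50 and 200 ms give the early
#' and late rate of force development.
#'
#' @param trace A [force_trace()].
#' @param onset_time Onset time in seconds (see [detect_onset()]).
#' @param window_ms Window length in milliseconds.
#' @return Rate of force development in N/s.
#' @export
rfd_window <- function(trace, onset_time, window_ms) {
  stopifnot(inherits(trace, "force_trace"))
  i0 <- trace_index(trace, onset_time)
  span <- round(window_ms / 1000 * trace$sample_rate)
  i1 <- i0 + span
  if (i1 > length(trace$force)) {
    stop(sprintf(
      "the %g ms window from onset extends past the trace end", window_ms
    ), call. = FALSE)
  }
  (trace$force[i1] - trace$force[i0]) / (window_ms / 1000)
}

#' Peak rate of force development
#'
#' Maximal windowed slope of force versus time between onset and the time of
#' maximal force, over all `slope_window_ms` windows (stride one sample).
#' The slope is the endpoint difference quotient by default; a least-squares
#' fit over the window is available via `method = "least_squares"`.
#'
#' If the force maximum is closer to the onset than one window (e.g. a flat
#' trace), the single window starting at onset is used; a constant trace
#' therefore yields 0 N/s.
#'
#' @param trace A [force_trace()].
#' @param onset_time Onset time in seconds.
#' @param slope_window_ms Differentiation window in milliseconds (default 20;
#'   must span at least 2 samples).
#' @param method `"endpoint"` (default) or `"least_squares"`.
#' @return Peak rate of force development in N/s.
#' @export
rfd_peak <- function(trace, onset_time, slope_window_ms = 20,
                     method = c("endpoint", "least_squares")) {
  stopifnot(inherits(trace, "force_trace"))
  method <- match.arg(method)
  fs <- trace$sample_rate
  w <- round(slope_window_ms / 1000 * fs)
  if (w < 1L || slope_window_ms / 1000 * fs < 1) {
    stop("slope window must span at least 2 samples", call. = FALSE)
  }
  i0 <- trace_index(trace, onset_time)
  n <- length(trace$force)
  if (i0 + w > n) {
    stop("slope window from onset extends past the trace end", call. = FALSE)
  }
  i_max <- which.max(trace$force)
  last_start <- max(i0, min(i_max - w, n - w))
  starts <- i0:last_start
  dt <- w / fs
  if (method == "endpoint") {
    slopes <- (trace$force[starts + w] - trace$force[starts]) / dt
  } else {
    tt <- (0:w) / fs
    sxx <- sum((tt - mean(tt))^2)
    tc <- tt - mean(tt)
    slopes <- vapply(starts, function(s) {
      sum(tc * (trace$force[s:(s + w)])) / sxx
    }, numeric(1))
  }
  max(slopes)
}

#' Isometric outcome metrics for one maximal push
#'
#' Runs the full isometric processing chain on a raw trace: zero-phase
#' low-pass filtering, baseline correction, onset detection, peak 500-ms
#' force epoch, and early/late/peak rate of force development.
#'
#' @param trace Raw [force_trace()] of one isometric push.
#' @param cutoff Filter cutoff in Hz (default 10).
#' @param baseline_ms Baseline window in ms (default 200).
#' @param threshold_fraction Onset threshold as a fraction of maximal force
#'   (default 0.01).
#' @param epoch_ms Peak-force epoch in ms (default 500).
#' @param rfd_windows_ms Early/late RFD windows in ms (default `c(50, 200)`).
#' @param slope_window_ms Peak-RFD differentiation window in ms (default 20).
#'
#' @return A list of class `isometric_metrics` with elements `pf_iso`,
#'   `rfd50`, `rfd200`, `rfd_peak`, `onset_time`, `max_force` (all on the
#'   filtered, baseline-corrected signal).
#' @export
isometric_metrics <- function(trace, cutoff = 10, baseline_ms = 200,
                              threshold_fraction = 0.01, epoch_ms = 500,
                              rfd_windows_ms = c(50, 200),
                              slope_window_ms = 20) {
  filtered <- lowpass_filter(trace, cutoff = cutoff)
  corrected <- baseline_correct(filtered, baseline_ms)
  onset <- detect_onset(corrected,
    threshold_fraction = threshold_fraction,
    baseline_ms = 0
  )
  out <- list(
    pf_iso = peak_force_epoch(corrected, epoch_ms),
    rfd50 = rfd_window(corrected, onset, rfd_windows_ms[1]),
    rfd200 = rfd_window(corrected, onset, rfd_windows_ms[2]),
    rfd_peak = rfd_peak(corrected, onset, slope_window_ms),
    onset_time = onset,
    max_force = max(corrected$force)
  )
  class(out) <- "isometric_metrics"
  out
}

#' @export
print.isometric_metrics <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<isometric_metrics> PF_iso %.1f N | RFD50 %.0f N/s | ",
      "RFD200 %.0f N/s | RFDpeak %.0f N/s | onset %.3f s\n"
    ),
    x$pf_iso, x$rfd50, x$rfd200, x$rfd_peak, x$onset_time
  ))
  invisible(x)
}
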