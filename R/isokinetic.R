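#' Nominal isokinetic phase timeline
#'
#' Builds the device command schedule for a set of machine-paced squat
#' repetitions: each repetition is a 4-s eccentric phase, a ~1-s pause at the
#' bottom, and a 4-s concentric phase, with a ~1-s pause at the top before the
#' next eccentric phase begins. Phase boundaries come from this schedule (the
#' device is position-controlled), not from the force signal.
#'
#' @param n_reps Number of repetitions (default 3).
#' @param rep_start Start time (s) of the first eccentric phase.
#' @param ecc_s,pause_s,con_s,top_pause_s Phase durations in seconds
#'   (defaults 4, 1, 4, 1).
#' @return A data.frame of class `phase_timeline` with columns `rep_index`,
#'   `label` (`eccentric`, `pause_bottom`, `concentric`, `pause_top`), `start`,
#'   `end` (seconds).
#' @export
#' @examples
#' phase_timeline(n_reps = 1)
phase_timeline <- function(n_reps = 3, rep_start = 0, ecc_s = 4, pause_s = 1,
                           con_s = 4, top_pause_s = 1) {
  stopifnot(n_reps >= 1, ecc_s > 0, pause_s > 0, con_s > 0, top_pause_s >= 0)
  rep_len <- ecc_s + pause_s + con_s + top_pause_s
  rows <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    s <- rep_start + (r - 1) * rep_len
    data.frame(
      rep_index = r,
      label = c("eccentric", "pause_bottom", "concentric", "pause_top"),
      start = s + c(0, ecc_s, ecc_s + pause_s, ecc_s + pause_s + con_s),
      end = s + c(ecc_s, ecc_s + pause_s, ecc_s + pause_s + con_s, rep_len),
      stringsAsFactors = FALSE
    )
  }))
  class(rows) <- c("phase_timeline", "data.frame")
  rows
}

#' Segment an isokinetic trace into phase annotations
#'
#' Clips a protocol timeline to the trace and returns the phase annotations
#' covering each repetition's eccentric/pause/concentric spans. A repetition
#' whose working phases (eccentric or concentric) extend beyond the recorded
#' trace is an error; trailing top pauses are silently clipped.
#'
#' @param trace A [force_trace()].
#' @param protocol A [phase_timeline()] (or data.frame with the same columns).
#' @return Data.frame of phase annotations (`rep_index`, `label`, `start`,
#'   `end`), non-overlapping within each rep.
#' @export
segment_isokinetic <- function(trace, protocol) {
  stopifnot(inherits(trace, "force_trace"))
  need <- c("rep_index", "label", "start", "end")
  if (!all(need %in% names(protocol))) {
    stop("protocol must supply rep_index, label, start, end", call. = FALSE)
  }
  t_end <- trace$t0 + trace_duration(trace)
  working <- protocol$label %in% c("eccentric", "concentric")
  over <- working & (protocol$end > t_end + 1e-9 | protocol$start < trace$t0 - 1e-9)
  if (any(over)) {
    bad <- sort(unique(protocol$rep_index[over]))
    stop(sprintf(
      "protocol extends beyond the trace for rep %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  out <- protocol
  out$start <- pmax(out$start, trace$t0)
  out$end <- pmin(out$end, t_end)
  out <- out[out$end > out$start, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal `epoch_ms` moving-mean force within [start, end) of a phase
phase_epoch_peak <- function(trace, start, end, epoch_ms) {
  i0 <- trace_index(trace, start)
  i1 <- trace_index(trace, end)
  w <- max(1L, round(epoch_ms / 1000 * trace$sample_rate))
  seg <- trace$force[i0:i1]
  if (length(seg) < w) {
    stop(sprintf(
      "phase [%.2f, %.2f] s shorter than the %g ms epoch", start, end, epoch_ms
    ), call. = FALSE)
  }
  max(moving_mean(seg, w))
}

#' Isokinetic peak forces from annotated phases
#'
#' For each analysed repetition, finds the highest mean force over a 25-ms
#' epoch within the concentric and eccentric phases, then averages across the
#' analysed repetitions. Repetitions 2 and 3 (the maximal-effort reps of the
#' analysed set) are used by default.
#'
#' @param trace A filtered [force_trace()].
#' @param phases Phase annotations from [segment_isokinetic()].
#' @param epoch_ms Epoch length in ms (default 25).
#' @param analysed_reps Integer vector of repetition indices to analyse
#'   (default `c(2, 3)`).
#' @return A list of class `isokinetic_metrics` with `pf_con`, `pf_ecc`
#'   (means across analysed reps, newtons) and `per_rep` (data.frame with
#'   `rep_index`, `pf_con`, `pf_ecc`).
#' @export
isokinetic_peaks <- function(trace, phases, epoch_ms = 25,
                             analysed_reps = c(2, 3)) {
  stopifnot(inherits(trace, "force_trace"))
  missing_reps <- setdiff(analysed_reps, unique(phases$rep_index))
  if (length(missing_reps)) {
    stop(sprintf(
      "analysed rep %s missing from phase annotations",
      paste(missing_reps, collapse = ", ")
    ), call. = FALSE)
  }
  per_rep <- do.call(rbind, lapply(sort(analysed_reps), function(r) {
    one <- function(lab) {
      ph <- phases[phases$rep_index == r & phases$label == lab, , drop = FALSE]
      if (nrow(ph) != 1L) {
        stop(sprintf("rep %d lacks a %s phase", r, lab), call. = FALSE)
      }
      phase_epoch_peak(trace, ph$start, ph$end, epoch_ms)
    }
    data.frame(
      rep_index = r,
      pf_con = one("concentric"),
      pf_ecc = one("eccentric")
    )
  }))
  out <- list(
    pf_con = mean(per_rep$pf_con),
    pf_ecc = mean(per_rep$pf_ecc),
    per_rep = per_rep
  )
  class(out) <- "isokinetic_metrics"
  out
}

#' @export
print.isokinetic_metrics <- function(x, ...) {
  cat(sprintf(
    "<isokinetic_metrics> PF_con %.1f N | PF_ecc %.1f N (%d reps analysed)\n",
    x$pf_con, x$pf_ecc, nrow(x$per_rep)
  ))
  invisible(x)
}
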