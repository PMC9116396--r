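#' Force-time trace
#'
#' Container for a uniformly sampled force-time series, the substrate for all
#' signal operations. Sample `i` (1-based) is taken at time
#' `t0 + (i - 1) / sample_rate`.
#'
#' @param force Numeric vector of force samples in newtons. At least 2
#'   samples, all finite.
#' @param sample_rate Sampling rate in Hz (default 1000, the load-cell rate).
#' @param t0 Time of the first sample in seconds.
#' @param meta Named list of free-form labels (participant, condition, trial
#'   kind, ...).
#'
#' @return An object of class `force_trace`.
#' @export
#' @examples
#' tr <- force_trace(rep(500, 3000))
#' trace_duration(tr)
force_trace <- function(force, sample_rate = 1000, t0 = 0, meta = list()) {
  force <- as.numeric(force)
  if (length(force) < 2L) {
    stop("a force_trace needs at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(force))) {
    stop("all force values must be finite", call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a single positive number", call. = FALSE)
  }
  structure(
    list(force = force, sample_rate = sample_rate, t0 = t0, meta = meta),
    class = "force_trace"
  )
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf(
    "<force_trace> %d samples @ %g Hz (%.3f s), range [%.1f, %.1f] N\n",
    length(x$force), x$sample_rate, trace_duration(x),
    min(x$force), max(x$force)
  ))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param trace A [force_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  trace$t0 + (seq_along(trace$force) - 1) / trace$sample_rate
}

#' Duration of a trace in seconds
#'
#' @param trace A [force_trace()].
#' @return Time spanned from first to last sample, in seconds.
#' @export
trace_duration <- function(trace) {
  stopifnot(inherits(trace, "force_trace"))
  (length(trace$force) - 1) / trace$sample_rate
}

# index of the sample closest to time t (1-based); errors outside the span
trace_index <- function(trace, t) {
  i <- round((t - trace$t0) * trace$sample_rate) + 1
  if (i < 1 || i > length(trace$force)) {
    stop(sprintf("time %.4f s outside trace span", t), call. = FALSE)
  }
  as.integer(i)
}

#' Read a force trace from CSV
#'
#' Reads a two-column `time_s,force_n` CSV (one trace per file), checking for
#' uniform sampling. An optional JSON sidecar (same path with extension
#' `.json`) supplies metadata.
#'
#' @param path Path to the CSV file.
#' @param meta Optional named list of metadata; merged over any sidecar.
#' @return A [force_trace()].
#' @export
read_force_trace <- function(path, meta = list()) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "force_n") %in% names(df))) {
    stop("trace CSV must have columns time_s and force_n", call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6 * mean(dt) + 1e-9) {
    stop("trace is not uniformly sampled", call. = FALSE)
  }
  sidecar <- sub("\\.csv$", ".json", path)
  side_meta <- if (file.exists(sidecar) && sidecar != path) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list()
  }
  side_meta[names(meta)] <- meta
  force_trace(df$force_n,
    sample_rate = 1 / mean(dt),
    t0 = df$time_s[1], meta = side_meta
  )
}

#' Write a force trace to CSV
#'
#' @param trace A [force_trace()].
#' @param path Output CSV path; metadata, if any, goes to a `.json` sidecar.
#' @return `path`, invisibly.
#' @export
write_force_trace <- function(trace, path) {
  stopifnot(inherits(trace, "force_trace"))
  utils::write.csv(
    data.frame(time_s = trace_times(trace), force_n = trace$force),
    path,
    row.names = FALSE
  )
  if (length(trace$meta)) {
    jsonlite::write_json(trace$meta, sub("\\.csv$", ".json", path),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}
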