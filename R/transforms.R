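#' Shapiro-Wilk normality screen
#'
#' Screens a residual (or raw) sample for normality with the Shapiro-Wilk
#' test; the verdict is `"non-normal"` when `p < alpha` (default 0.05).
#'
#' @param residuals Numeric vector, 3 to 5000 finite values.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A list with `W` (statistic), `p` (p-value) and `verdict`
#'   (`"normal"` / `"non-normal"`).
#' @export
assess_normality <- function(residuals, alpha = 0.05) {
  x <- residuals[is.finite(residuals)]
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop(sprintf(
      "Shapiro-Wilk supports 3 <= n <= 5000 (got %d finite values)", n
    ), call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  list(
    W = unname(sw$statistic),
    p = sw$p.value,
    verdict = if (sw$p.value < alpha) "non-normal" else "normal"
  )
}

new_transform_record <- function(kind, parameters, note = "") {
  structure(
    list(kind = kind, parameters = parameters, note = note),
    class = "transform_record"
  )
}

#' @export
print.transform_record <- function(x, ...) {
  cat(sprintf("<transform_record> %s %s\n", x$kind, x$note))
  invisible(x)
}

#' Shifted-log normalizing transform
#'
#' Natural log of `value + offset`. The offset is 0 when all values are
#' positive; otherwise `|min| + max(1e-8, 1e-3 * range)` so the smallest
#' shifted value stays strictly positive. The offset is recorded for exact
#' inversion.
#'
#' @param values Numeric vector (length >= 1, not all equal).
#' @param offset Optional fixed offset overriding the rule above.
#' @return List with `values` (transformed) and `record`
#'   (a `transform_record`).
#' @export
log_x_transform <- function(values, offset = NULL) {
  x <- as.numeric(values)
  if (length(x) < 1L || !all(is.finite(x))) {
    stop("values must be finite and non-empty", call. = FALSE)
  }
  if (length(x) > 1L && diff(range(x)) == 0) {
    stop("degenerate input: all values equal", call. = FALSE)
  }
  if (is.null(offset)) {
    offset <- if (min(x) > 0) 0 else abs(min(x)) + max(1e-8, 1e-3 * diff(range(x)))
  }
  rec <- new_transform_record("log_x", list(offset = offset),
    note = sprintf("offset %.6g", offset)
  )
  list(values = log(x + offset), record = rec)
}

#' Ordered-quantile (rank-based inverse normal) transform
#'
#' Maps each value to the standard-normal quantile of its mid-rank position
#' `(r - 0.5) / n` (ties share averaged ranks), producing a sample that is
#' near-exactly normal whatever the source distribution. The sorted training
#' values and their normal scores are stored so new data can be transformed
#' (and transformed data inverted) by linear interpolation.
#'
#' @param values Numeric vector, length >= 3, not all identical.
#' @param rank_offset Plotting-position convention: `"midpoint"` uses
#'   `(r - 0.5)/n` (default), `"blom_simple"` uses `r/(n + 1)`.
#' @return List with `values` (normal scores, order-preserving) and `record`.
#' @export
ordered_quantile_transform <- function(values,
                                       rank_offset = c("midpoint", "blom_simple")) {
  rank_offset <- match.arg(rank_offset)
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3L || !all(is.finite(x))) {
    stop("need >= 3 finite values", call. = FALSE)
  }
  if (diff(range(x)) == 0) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  r <- rank(x, ties.method = "average")
  pp <- if (rank_offset == "midpoint") (r - 0.5) / n else r / (n + 1)
  g <- stats::qnorm(pp)
  # training map for interpolation on new data: x -> score actually assigned
  o <- order(x)
  rec <- new_transform_record(
    "ordered_quantile",
    list(
      train_x = x[o], train_g = g[o],
      rank_offset = rank_offset, n = n
    ),
    note = sprintf("n = %d, %s plotting positions", n, rank_offset)
  )
  list(values = g, record = rec)
}

#' Apply a stored transform to new values
#'
#' Log transforms apply exactly; ordered-quantile transforms interpolate
#' linearly on the stored training mapping (clamped at the training range).
#'
#' @param record A `transform_record`.
#' @param values Numeric vector to transform.
#' @return Transformed values.
#' @export
apply_transform <- function(record, values) {
  stopifnot(inherits(record, "transform_record"))
  switch(record$kind,
    identity = values,
    log_x = log(values + record$parameters$offset),
    ordered_quantile = {
      p <- record$parameters
      stats::approx(p$train_x, p$train_g,
        xout = values, rule = 2, ties = mean
      )$y
    },
    stop("unknown transform kind: ", record$kind, call. = FALSE)
  )
}

#' Invert a stored transform
#'
#' @param record A `transform_record`.
#' @param values Transformed values to map back to the original scale.
#' @return Back-transformed values (exact for log, interpolated for
#'   ordered-quantile).
#' @export
invert_transform <- function(record, values) {
  stopifnot(inherits(record, "transform_record"))
  switch(record$kind,
    identity = values,
    log_x = exp(values) - record$parameters$offset,
    ordered_quantile = {
      p <- record$parameters
      stats::approx(p$train_g, p$train_x,
        xout = values, rule = 2, ties = mean
      )$y
    },
    stop("unknown transform kind: ", record$kind, call. = FALSE)
  )
}

#' Serialize / restore a transform record
#'
#' @param record A `transform_record`.
#' @param path JSON path.
#' @return `write_transform_record()` returns `path` invisibly;
#'   `read_transform_record()` returns the restored record.
#' @export
write_transform_record <- function(record, path) {
  stopifnot(inherits(record, "transform_record"))
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_record
#' @export
read_transform_record <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_transform_record(obj$kind, as.list(obj$parameters), obj$note %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Residual-driven transform selection
#'
#' Implements the transform policy used for the trial outcomes: keep the raw
#' scale unless residual normality is rejected (Shapiro-Wilk `p < alpha`) AND
#' a candidate transform improves normality (higher residual `W`). Candidates
#' are the shifted log and the ordered-quantile transform; whichever yields
#' the higher residual `W` wins.
#'
#' @param fit_residuals Function taking a numeric vector of (possibly
#'   transformed) outcome values and returning model residuals for them.
#' @param values Raw outcome values.
#' @param alpha Rejection level for the normality screen (default 0.05).
#' @return List with `kind` (chosen transform), `values` (outcome on the
#'   analysis scale), `record`, and `screen` (per-candidate Shapiro results).
#' @export
select_transform <- function(fit_residuals, values, alpha = 0.05) {
  raw <- assess_normality(fit_residuals(values), alpha = alpha)
  screen <- list(identity = raw)
  if (raw$verdict == "normal") {
    return(list(
      kind = "identity", values = values,
      record = new_transform_record("identity", list()), screen = screen
    ))
  }
  cands <- list(
    log_x = log_x_transform(values),
    ordered_quantile = ordered_quantile_transform(values)
  )
  for (k in names(cands)) {
    screen[[k]] <- tryCatch(
      assess_normality(fit_residuals(cands[[k]]$values), alpha = alpha),
      error = function(e) list(W = -Inf, p = NA_real_, verdict = "error")
    )
  }
  ws <- vapply(screen[c("log_x", "ordered_quantile")], `[[`, numeric(1), "W")
  best <- names(which.max(ws))
  if (max(ws) <= raw$W) {
    return(list(
      kind = "identity", values = values,
      record = new_transform_record("identity", list()), screen = screen
    ))
  }
  list(
    kind = best, values = cands[[best]]$values,
    record = cands[[best]]$record, screen = screen
  )
}
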