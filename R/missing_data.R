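#' Invalidate records by named rules
#'
#' Applies named predicates to the trial table and sets the outcome `value`
#' of matching rows to missing (rows are never deleted), e.g. a
#' wrong-load flag on a repetitions-to-failure record. Returns the data plus
#' a missingness report enumerating each removal and its reason.
#'
#' @param data Trial table (long format with a `value` column).
#' @param rules Named list of predicate functions; each takes the data frame
#'   and returns a logical vector over rows.
#' @return List with `data` (outcomes invalidated to `NA`) and `report`
#'   (a `missingness_report`).
#' @export
invalidate_records <- function(data, rules = list()) {
  if (!"value" %in% names(data)) {
    stop("data must have a value column", call. = FALSE)
  }
  removed <- list()
  for (nm in names(rules)) {
    hit <- tryCatch(rules[[nm]](data), error = function(e) {
      stop(sprintf("rule '%s' failed: %s", nm, conditionMessage(e)),
        call. = FALSE
      )
    })
    if (!is.logical(hit) || length(hit) != nrow(data)) {
      stop(sprintf("rule '%s' must return one logical per row", nm),
        call. = FALSE
      )
    }
    hit <- which(hit & !is.na(data$value))
    if (length(hit)) {
      removed[[nm]] <- hit
      data$value[hit] <- NA_real_
    }
  }
  list(data = data, report = missingness_report(data, removed))
}

#' Missingness report for a trial table
#'
#' @param data Trial table with `value` (and optionally `outcome`) columns.
#' @param removed Optional named list of row indices invalidated per rule.
#' @return A `missingness_report`: `n_total`, `n_missing`, `fraction`,
#'   `per_outcome` breakdown, and `removed` (rule, rows, reason).
#' @export
missingness_report <- function(data, removed = list()) {
  n_total <- nrow(data)
  n_missing <- sum(is.na(data$value))
  per_outcome <- if ("outcome" %in% names(data)) {
    agg <- stats::aggregate(
      is.na(data$value),
      by = list(outcome = data$outcome), FUN = function(z) c(sum(z), length(z))
    )
    data.frame(
      outcome = agg$outcome,
      n_missing = agg$x[, 1],
      n_total = agg$x[, 2],
      fraction = agg$x[, 1] / agg$x[, 2],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      outcome = "value", n_missing = n_missing, n_total = n_total,
      fraction = if (n_total > 0) n_missing / n_total else NA_real_
    )
  }
  structure(
    list(
      n_total = n_total,
      n_missing = n_missing,
      fraction = if (n_total > 0) n_missing / n_total else NA_real_,
      per_outcome = per_outcome,
      removed = lapply(names(removed), function(nm) {
        list(reason = nm, rows = removed[[nm]], n = length(removed[[nm]]))
      })
    ),
    class = "missingness_report"
  )
}

#' @export
print.missingness_report <- function(x, ...) {
  cat(sprintf(
    "<missingness_report> %d of %d values missing (%.1f%%), %d invalidation rule(s)\n",
    x$n_missing, x$n_total, 100 * x$fraction, length(x$removed)
  ))
  invisible(x)
}

#' Write a missingness report to JSON
#'
#' @param report A `missingness_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_missingness_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}

#' Multiple imputation by predictive-mean matching
#'
#' Fills missing outcome values with `m` stochastic completions, preserving
#' the full sample size. Within each outcome, a Bayesian linear model of the
#' observed values on condition, sex, visit, timepoint (when present) and the
#' participant's mean observed value predicts every cell; each missing cell
#' takes the observed value of a donor drawn from the `k` observed cells
#' whose predictions are nearest (predictive-mean matching), so imputations
#' respect the outcome's observed support. Observed cells are never altered.
#'
#' @param data Trial table (long format: `participant_id`, `condition`,
#'   `sex`, `visit`, optionally `timepoint`, `outcome`, `value`).
#' @param m Number of imputed datasets (default 100).
#' @param seed Integer seed; completions are reproducible given the seed.
#' @param k Donor-pool size for predictive-mean matching (default 5).
#' @param bounds Optional `c(lower, upper)` clamp applied to imputed values
#'   (e.g. `c(0, 100)` for visual-analog-scale scores).
#' @param bounds_outcomes Optional character vector: outcomes the clamp
#'   applies to (default: all outcomes when `bounds` is given).
#' @return List of `m` completed trial tables (zero missing outcome values).
#' @export
impute <- function(data, m = 100, seed = 1, k = 5, bounds = NULL,
                   bounds_outcomes = NULL) {
  if (!"value" %in% names(data)) {
    stop("data must have a value column", call. = FALSE)
  }
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  outcomes <- if ("outcome" %in% names(data)) unique(data$outcome) else "value"
  for (oc in outcomes) {
    sel <- if ("outcome" %in% names(data)) data$outcome == oc else TRUE
    v <- data$value[sel]
    if (all(is.na(v))) {
      stop(sprintf("outcome '%s' is entirely missing", oc), call. = FALSE)
    }
    frac <- mean(is.na(v))
    if (frac >= 0.5) {
      stop(sprintf(
        "outcome '%s' is %.0f%% missing (>= 50%%)", oc, 100 * frac
      ), call. = FALSE)
    }
  }
  if (!anyNA(data$value)) {
    return(replicate(m, data, simplify = FALSE))
  }
  set.seed(seed)
  lapply(seq_len(m), function(i) {
    impute_once(data, k = k, bounds = bounds, bounds_outcomes = bounds_outcomes)
  })
}

# one stochastic completion (consumes the current RNG stream)
impute_once <- function(data, k = 5, bounds = NULL, bounds_outcomes = NULL) {
  out <- data
  outcomes <- if ("outcome" %in% names(data)) unique(data$outcome) else "value"
  for (oc in outcomes) {
    sel <- if ("outcome" %in% names(data)) which(data$outcome == oc) else seq_len(nrow(data))
    sub <- data[sel, , drop = FALSE]
    mis <- is.na(sub$value)
    if (!any(mis)) next
    X <- pmm_design(sub)
    obs <- which(!mis)
    Xo <- X[obs, , drop = FALSE]
    yo <- sub$value[obs]
    qrX <- qr(Xo)
    keep <- qrX$pivot[seq_len(qrX$rank)]
    Xo <- Xo[, keep, drop = FALSE]
    Xa <- X[, keep, drop = FALSE]
    fit <- stats::lm.fit(Xo, yo)
    dfres <- max(1L, length(yo) - ncol(Xo))
    s2 <- sum(fit$residuals^2) / dfres
    # Bayesian draw of (sigma^2, beta) for proper imputation
    s2_star <- s2 * dfres / stats::rchisq(1, dfres)
    XtXinv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
    beta_star <- fit$coefficients +
      drop(chol(s2_star * XtXinv) %*% stats::rnorm(ncol(Xo)))
    pred <- drop(Xa %*% beta_star)
    clamp <- !is.null(bounds) &&
      (is.null(bounds_outcomes) || oc %in% bounds_outcomes)
    for (j in which(mis)) {
      d <- abs(pred[obs] - pred[j])
      donors <- obs[order(d)][seq_len(min(k, length(obs)))]
      pick <- sub$value[sample(donors, 1)]
      if (clamp) pick <- min(max(pick, bounds[1]), bounds[2])
      out$value[sel[j]] <- pick
    }
  }
  out
}

# imputation design: trial factors plus the participant's observed mean
pmm_design <- function(sub) {
  fac <- list(intercept = rep(1, nrow(sub)))
  for (col in c("condition", "sex", "visit", "timepoint")) {
    if (col %in% names(sub) && length(unique(sub[[col]])) > 1L) {
      mm <- stats::model.matrix(~f, data.frame(f = factor(sub[[col]])))[, -1, drop = FALSE]
      colnames(mm) <- paste0(col, seq_len(ncol(mm)))
      fac[[col]] <- mm
    }
  }
  pmean <- tapply(sub$value, sub$participant_id, function(v) mean(v, na.rm = TRUE))
  pm <- pmean[as.character(sub$participant_id)]
  pm[!is.finite(pm)] <- mean(sub$value, na.rm = TRUE)
  fac$participant_mean <- as.numeric(pm)
  do.call(cbind, fac)
}

#' Pool mixed-model fits across imputations (Rubin's rules)
#'
#' Combines `m >= 2` fits of the same model on multiply imputed datasets:
#' the pooled estimate is the mean of the per-fit estimates, the pooled
#' variance is the mean within-imputation variance plus `(1 + 1/m)` times the
#' between-imputation variance, and intervals/p-values use the
#' Barnard-Rubin degrees of freedom (normal critical values for the 95% CI,
#' matching the single-fit convention).
#'
#' @param fits List of `fit_result` objects with identical coefficient sets.
#' @return A pooled `fit_result` (variance components and R-squared averaged
#'   across fits; `method = "rubin_pooled"`).
#' @export
pool_fits <- function(fits) {
  if (length(fits) < 2L) {
    stop("pooling needs >= 2 fits", call. = FALSE)
  }
  terms0 <- fits[[1]]$coefficients$term
  for (f in fits) {
    if (!identical(f$coefficients$term, terms0)) {
      stop("fits have mismatched coefficient sets", call. = FALSE)
    }
  }
  m <- length(fits)
  est <- sapply(fits, function(f) f$coefficients$estimate)
  vw <- sapply(fits, function(f) f$coefficients$se^2)
  if (is.null(dim(est))) {
    est <- matrix(est, nrow = 1)
    vw <- matrix(vw, nrow = 1)
  }
  qbar <- rowMeans(est)
  wbar <- rowMeans(vw)
  bvar <- apply(est, 1, stats::var)
  tvar <- wbar + (1 + 1 / m) * bvar
  se <- sqrt(tvar)
  r <- ifelse(bvar > 0, (1 + 1 / m) * bvar / wbar, 0)
  df <- ifelse(r > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  tval <- qbar / se
  mean_of <- function(field) mean(vapply(fits, `[[`, numeric(1), field))
  new_fit_result(
    coefficients = data.frame(
      term = terms0,
      estimate = qbar,
      se = se,
      df = df,
      ci_low = qbar - stats::qnorm(0.975) * se,
      ci_high = qbar + stats::qnorm(0.975) * se,
      p = 2 * stats::pt(-abs(tval), df),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    var_participant = mean_of("var_participant"),
    var_residual = mean_of("var_residual"),
    phi = mean(vapply(fits, `[[`, numeric(1), "phi")),
    var_fixed = mean_of("var_fixed"),
    logLik = NA_real_,
    fallback = any(vapply(fits, function(f) isTRUE(f$fallback), logical(1))),
    converged = all(vapply(fits, function(f) isTRUE(f$converged), logical(1))),
    n_obs = fits[[1]]$n_obs,
    n_groups = fits[[1]]$n_groups,
    method = "rubin_pooled",
    spec = fits[[1]]$spec,
    m = m
  )
}
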