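#' Fit the crossover linear mixed model (single-value outcomes)
#'
#' REML fit of the crossover model with fixed effects for condition, sex,
#' their interaction, visit (period), and the two coded carryover variables,
#' with a random intercept per participant and independent residuals. The
#' fit is delegated to [nlme::lme()]; coefficients are reported with Wald 95%
#' confidence intervals (normal critical values) and two-sided p-values.
#'
#' @param spec A `model_spec` from [build_design()].
#' @param data Trial records with the columns named in the spec and a `value`
#'   column. Must be complete (impute first; see [impute()]).
#' @return A `fit_result`: `coefficients` (term, estimate, se, df, ci_low,
#'   ci_high, p), `var_participant`, `var_residual`, `phi` (`NA` here),
#'   `var_fixed`, `logLik`, `r2_marginal`, `r2_conditional`, `fallback`,
#'   `converged`, `n_obs`, `n_groups`, `method`.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  d <- design_factors(data, spec$kind)
  if (anyNA(d$value)) {
    stop("data contain missing outcome values; impute or drop them first",
      call. = FALSE
    )
  }
  check_rank(spec$fixed, d)
  per <- table(d$participant_id)
  if (any(per < 2)) {
    stop("each participant needs >= 2 observations", call. = FALSE)
  }
  fit <- tryCatch(
    nlme::lme(spec$fixed,
      random = ~ 1 | participant_id, data = d,
      method = "REML"
    ),
    error = function(e) {
      stop("mixed-model fit did not converge: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  tt <- summary(fit)$tTable
  beta <- nlme::fixef(fit)
  X <- stats::model.matrix(spec$fixed, d)
  vc <- nlme::VarCorr(fit)
  sd_b <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
  sigma_e <- fit$sigma
  new_fit_result(
    coefficients = data.frame(
      term = rownames(tt),
      estimate = tt[, "Value"],
      se = tt[, "Std.Error"],
      df = tt[, "DF"],
      ci_low = tt[, "Value"] - stats::qnorm(0.975) * tt[, "Std.Error"],
      ci_high = tt[, "Value"] + stats::qnorm(0.975) * tt[, "Std.Error"],
      p = tt[, "p-value"],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    var_participant = sd_b^2,
    var_residual = sigma_e^2,
    phi = NA_real_,
    var_fixed = stats::var(as.numeric(X %*% beta)),
    logLik = as.numeric(stats::logLik(fit)),
    fallback = FALSE,
    converged = TRUE,
    n_obs = nrow(d),
    n_groups = length(unique(d$participant_id)),
    method = "nlme_lme",
    spec = spec
  )
}

new_fit_result <- function(...) {
  out <- list(...)
  tot <- out$var_fixed + out$var_participant + out$var_residual
  if (!is.finite(tot) || tot <= 0) {
    stop("undefined R-squared: zero total variance", call. = FALSE)
  }
  out$r2_marginal <- out$var_fixed / tot
  out$r2_conditional <- (out$var_fixed + out$var_participant) / tot
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> %s via %s%s: %d terms, n = %d, groups = %d\n",
    x$spec$outcome %||% "outcome", x$method,
    if (isTRUE(x$fallback)) " (AR1 fallback -> independent)" else "",
    nrow(x$coefficients), x$n_obs, x$n_groups
  ))
  cat(sprintf(
    "  var(participant) = %.3g, var(residual) = %.3g, phi = %s\n",
    x$var_participant, x$var_residual,
    if (is.na(x$phi)) "-" else sprintf("%.3f", x$phi)
  ))
  cat(sprintf(
    "  R2 marginal = %.3f, conditional = %.3f\n",
    x$r2_marginal, x$r2_conditional
  ))
  invisible(x)
}

check_rank <- function(fixed, d) {
  mm <- stats::model.matrix(fixed, d)
  dec <- qr(mm)
  if (dec$rank < ncol(mm)) {
    dropped <- colnames(mm)[dec$pivot[(dec$rank + 1):ncol(mm)]]
    stop(sprintf(
      "design matrix rank deficient; aliased columns: %s",
      paste(dropped, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(mm)
}

# ---- direct AR1 REML machinery -------------------------------------------

# Pack the data into per-participant blocks ordered by condition, timepoint.
# Within a participant, residual correlation is AR1 within each condition's
# timepoint series; the random intercept spans the whole participant block.
ar1_blocks <- function(fixed, d) {
  ord <- order(d$participant_id, d$condition, as.integer(as.character(d$timepoint)))
  d <- d[ord, , drop = FALSE]
  X <- stats::model.matrix(fixed, d)
  y <- d$value
  ids <- unique(d$participant_id)
  blocks <- lapply(ids, function(id) {
    sel <- which(d$participant_id == id)
    sub <- d[sel, , drop = FALSE]
    key <- as.character(sub$condition)
    list(
      idx = sel,
      series = split(as.integer(as.character(sub$timepoint)), key)[unique(key)]
    )
  })
  list(d = d, X = X, y = y, blocks = blocks, n = nrow(d), p = ncol(X))
}

# AR1 correlation matrix for integer timepoints (lag = |t_j - t_k|)
ar1_corr <- function(times, phi) {
  phi^abs(outer(times, times, "-"))
}

# Exact -2 * restricted log-likelihood at given variance components.
# sigma_b2: participant-intercept variance; sigma_e2: residual variance;
# phi: AR1 coefficient within participant x condition over timepoint.
reml_neg2 <- function(bl, sigma_b2, sigma_e2, phi) {
  if (sigma_e2 <= 0 || sigma_b2 < 0 || abs(phi) >= 1) {
    return(Inf)
  }
  lambda <- sigma_b2 / sigma_e2
  agg <- ar1_aggregate(bl, lambda, phi)
  if (is.null(agg)) {
    return(Inf)
  }
  n <- bl$n
  p <- bl$p
  beta <- solve(agg$XtVX, agg$XtVy)
  rss <- agg$ytVy - sum(agg$XtVy * beta)
  (n - p) * log(2 * pi) + n * log(sigma_e2) + agg$logdetV -
    p * log(sigma_e2) + determinant(agg$XtVX, logarithm = TRUE)$modulus[1] +
    rss / sigma_e2
}

# accumulate X'V^-1 X, X'V^-1 y, y'V^-1 y and log|V| over participant blocks
# for V_i = lambda * J + blockdiag(AR1(phi)); returns NULL when a block's
# covariance is numerically non-positive-definite
ar1_aggregate <- function(bl, lambda, phi) {
  p <- bl$p
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ytVy <- 0
  logdetV <- 0
  for (b in bl$blocks) {
    m <- length(b$idx)
    R <- matrix(0, m, m)
    at <- 0
    for (tp in b$series) {
      k <- length(tp)
      R[(at + 1):(at + k), (at + 1):(at + k)] <- ar1_corr(tp, phi)
      at <- at + k
    }
    V <- R + lambda
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) {
      return(NULL)
    }
    Xi <- bl$X[b$idx, , drop = FALSE]
    yi <- bl$y[b$idx]
    Zx <- backsolve(ch, Xi, transpose = TRUE)
    zy <- backsolve(ch, yi, transpose = TRUE)
    XtVX <- XtVX + crossprod(Zx)
    XtVy <- XtVy + crossprod(Zx, zy)[, 1]
    ytVy <- ytVy + sum(zy^2)
    logdetV <- logdetV + 2 * sum(log(diag(ch)))
  }
  list(XtVX = XtVX, XtVy = XtVy, ytVy = ytVy, logdetV = logdetV)
}

# profiled objective over theta = (log lambda, atanh phi); sigma_e2 profiled
ar1_profiled_obj <- function(bl) {
  n <- bl$n
  p <- bl$p
  function(theta) {
    lambda <- exp(theta[1])
    phi <- tanh(theta[2])
    agg <- ar1_aggregate(bl, lambda, phi)
    if (is.null(agg)) {
      return(1e10)
    }
    beta <- tryCatch(solve(agg$XtVX, agg$XtVy), error = function(e) NULL)
    if (is.null(beta)) {
      return(1e10)
    }
    rss <- agg$ytVy - sum(agg$XtVy * beta)
    if (rss <= 0) {
      return(1e10)
    }
    ld <- determinant(agg$XtVX, logarithm = TRUE)$modulus[1]
    (n - p) * log(rss / (n - p)) + agg$logdetV + ld
  }
}

#' Fit the repeated-measures crossover model with AR1 residuals
#'
#' REML fit of the visual-analog-scale model: the single-outcome fixed
#' effects plus timepoint and its interactions, a random intercept per
#' participant, and a first-order autoregressive residual correlation within
#' each participant x condition timepoint series. The AR1 restricted
#' likelihood is profiled over the fixed effects and residual variance and
#' optimized over the intercept-to-residual variance ratio and the AR1
#' coefficient.
#'
#' When the curvature of the restricted likelihood at the optimum is not
#' positive definite (so interval estimates for the covariance parameters are
#' unobtainable), the model is refit with independent residuals via
#' [fit_lmm()] and the result carries `fallback = TRUE`.
#'
#' @param spec A repeated-outcome `model_spec` from [build_design()].
#' @param data Complete trial records including `timepoint`.
#' @return A `fit_result` (see [fit_lmm()]) with `phi` set, plus
#'   `reml_neg2` (the minimized -2 restricted log-likelihood).
#' @export
fit_vas_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$kind != "repeated") {
    stop("fit_vas_lmm needs a repeated-outcome model_spec", call. = FALSE)
  }
  d <- design_factors(data, "repeated")
  if (anyNA(d$value)) {
    stop("data contain missing outcome values; impute or drop them first",
      call. = FALSE
    )
  }
  series_len <- tapply(
    d$timepoint, interaction(d$participant_id, d$condition, drop = TRUE),
    function(x) length(unique(x))
  )
  if (all(series_len < 2)) {
    stop("AR1 unidentifiable: every participant x condition series has a single timepoint",
      call. = FALSE
    )
  }
  if (spec$correlation == "independent") {
    return(fit_lmm(spec, data))
  }
  check_rank(spec$fixed, d)
  bl <- ar1_blocks(spec$fixed, d)
  obj <- ar1_profiled_obj(bl)
  starts <- list(c(0, 0), c(log(0.5), atanh(0.5)), c(log(2), atanh(-0.3)))
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
        control = list(maxit = 500, reltol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  ok <- !is.null(best) && best$value < 1e9 && best$convergence == 0
  if (ok) {
    h <- tryCatch(num_hessian(obj, best$par), error = function(e) NULL)
    ok <- !is.null(h) && all(is.finite(h)) && all(eigen(h, symmetric = TRUE,
      only.values = TRUE
    )$values > 0)
  }
  if (!ok) {
    res <- fit_lmm(spec, data)
    res$fallback <- TRUE
    res$method <- "nlme_lme (AR1 fallback)"
    return(res)
  }
  lambda <- exp(best$par[1])
  phi <- tanh(best$par[2])
  agg <- ar1_aggregate(bl, lambda, phi)
  beta <- solve(agg$XtVX, agg$XtVy)
  rss <- agg$ytVy - sum(agg$XtVy * beta)
  sigma_e2 <- rss / (bl$n - bl$p)
  vcov_beta <- sigma_e2 * solve(agg$XtVX)
  se <- sqrt(diag(vcov_beta))
  df <- bl$n - length(bl$blocks) - bl$p + 1
  tval <- beta / se
  neg2 <- reml_neg2(bl, lambda * sigma_e2, sigma_e2, phi)
  new_fit_result(
    coefficients = data.frame(
      term = colnames(bl$X),
      estimate = as.numeric(beta),
      se = se,
      df = df,
      ci_low = as.numeric(beta) - stats::qnorm(0.975) * se,
      ci_high = as.numeric(beta) + stats::qnorm(0.975) * se,
      p = 2 * stats::pt(-abs(tval), df),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    var_participant = lambda * sigma_e2,
    var_residual = sigma_e2,
    phi = phi,
    var_fixed = stats::var(as.numeric(bl$X %*% beta)),
    logLik = -neg2 / 2,
    fallback = FALSE,
    converged = TRUE,
    n_obs = bl$n,
    n_groups = length(bl$blocks),
    method = "direct_ar1_reml",
    spec = spec,
    reml_neg2 = neg2,
    blocks = bl
  )
}

# central-difference Hessian of f at x (small, 2-parameter use)
num_hessian <- function(f, x, eps = 1e-4) {
  k <- length(x)
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ei <- ej <- numeric(k)
      ei[i] <- eps
      ej[j] <- eps
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / eps^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
            (4 * eps^2)
      }
    }
  }
  H
}

#' Evaluate the AR1 restricted likelihood at given variance components
#'
#' Exact -2 restricted log-likelihood of a fitted repeated-measures model at
#' arbitrary variance components, used to verify that the returned estimate
#' is a local optimum.
#'
#' @param fit A `fit_result` from [fit_vas_lmm()] (direct AR1 path).
#' @param var_participant,var_residual,phi Variance components to evaluate.
#' @return -2 restricted log-likelihood (smaller is better).
#' @export
reml_criterion <- function(fit, var_participant, var_residual, phi) {
  if (is.null(fit$blocks)) {
    stop("reml_criterion needs a direct AR1 fit", call. = FALSE)
  }
  reml_neg2(fit$blocks, var_participant, var_residual, phi)
}

#' Marginal and conditional R-squared for a mixed-model fit
#'
#' Variance-partition R-squared for random-intercept models: the marginal
#' value is the share of total variance explained by the fixed effects,
#' `var(fixed predictions) / (var(fixed) + var(participant) + var(residual))`;
#' the conditional value adds the participant-intercept variance to the
#' numerator.
#'
#' @param fit A `fit_result`.
#' @return List with `marginal` and `conditional`, both in `[0, 1]` with
#'   `marginal <= conditional`.
#' @export
nakagawa_r2 <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  list(marginal = fit$r2_marginal, conditional = fit$r2_conditional)
}

#' @rdname nakagawa_r2
#' @param var_fixed,var_participant,var_residual Variance components.
#' @export
nakagawa_r2_components <- function(var_fixed, var_participant, var_residual) {
  tot <- var_fixed + var_participant + var_residual
  if (!is.finite(tot) || tot <= 0) {
    stop("undefined R-squared: zero total variance", call. = FALSE)
  }
  list(
    marginal = var_fixed / tot,
    conditional = (var_fixed + var_participant) / tot
  )
}

#' Significance stars for a p-value
#'
#' Display rule: `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05
#' (inclusive thresholds), empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***",
    ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", ""))
  )
}

#' Coefficient summary of a fit
#'
#' One row per coefficient with estimate, 95% CI, p-value and significance
#' stars, in the layout of a coefficient table or a forest-plot value set.
#'
#' @param fit A `fit_result`.
#' @param style `"coefficient_table"` (adds se, df, and the R-squared values
#'   as attributes) or `"forest_values"` (term, b, CI, stars only).
#' @return A data.frame of report rows.
#' @export
summarize_fit <- function(fit, style = c("coefficient_table", "forest_values")) {
  stopifnot(inherits(fit, "fit_result"))
  style <- match.arg(style)
  co <- fit$coefficients
  if (nrow(co) == 0L) {
    return(data.frame(
      term = character(), b = numeric(), ci_low = numeric(),
      ci_high = numeric(), p = numeric(), stars = character()
    ))
  }
  base <- data.frame(
    term = co$term, b = co$estimate, ci_low = co$ci_low,
    ci_high = co$ci_high, p = co$p, stars = significance_stars(co$p),
    stringsAsFactors = FALSE
  )
  if (style == "forest_values") {
    return(base)
  }
  base$se <- co$se
  base$df <- co$df
  attr(base, "r2_marginal") <- fit$r2_marginal
  attr(base, "r2_conditional") <- fit$r2_conditional
  base
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  keep <- c(
    "coefficients", "var_participant", "var_residual", "phi", "var_fixed",
    "logLik", "r2_marginal", "r2_conditional", "fallback", "converged",
    "n_obs", "n_groups", "method"
  )
  obj <- fit[keep]
  obj$outcome <- fit$spec$outcome %||% NA_character_
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null"
  )
  invisible(path)
}
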