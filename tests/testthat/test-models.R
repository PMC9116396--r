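make_single <- function(seed, ...) {
  sim <- simulate_crossover_trial(one_outcome_config(seed, ...))
  sim$data
}

test_that("REML fit interpolates noiseless data exactly", {
  oc <- list(y = single_outcome_params(100, 5, 3, 10,
    c_sex = 2, nc_sex = 1, visit2 = 0.5, visit3 = 1,
    x1_effect = 0.7, x2_effect = 0.3, sd_participant = 1e-6, sd_residual = 1e-6
  ))
  cfg <- simulation_config(seed = 2, single_outcomes = oc,
    vas_outcomes = list(), missing_rate = 0
  )
  d <- simulate_crossover_trial(cfg)$data
  fit <- fit_lmm(build_design(d, "single", outcome = "y"), d)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  truth <- c(
    "(Intercept)" = 100, conditionC = 5, conditionNC = 3, sexmale = 10,
    x1 = 0.7, x2 = 0.3, "conditionC:sexmale" = 2
  )
  expect_lt(max(abs(est[names(truth)] - truth)), 1e-6)
})

test_that("condition-only fit equals the paired within-participant difference", {
  d <- make_single(21, effect_c = 5, effect_nc = 2)
  spec <- build_design(d, "single", outcome = "y")
  spec$fixed <- value ~ condition
  fit <- fit_lmm(spec, d)
  # balanced complete data: GLS reduces to the paired mean difference
  wide <- reshape(d[, c("participant_id", "condition", "value")],
    idvar = "participant_id", timevar = "condition", direction = "wide"
  )
  expect_equal(
    fit$coefficients$estimate[fit$coefficients$term == "conditionC"],
    mean(wide$value.C - wide$value.P),
    tolerance = 1e-8
  )
  expect_equal(
    fit$coefficients$estimate[fit$coefficients$term == "conditionNC"],
    mean(wide$value.NC - wide$value.P),
    tolerance = 1e-8
  )
})

test_that("estimates are invariant to relabelling participant IDs", {
  d <- make_single(31)
  fit1 <- fit_lmm(build_design(d, "single"), d)
  d2 <- d
  d2$participant_id <- sprintf("Z%s", d$participant_id)
  fit2 <- fit_lmm(build_design(d2, "single"), d2)
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
    tolerance = 1e-10
  )
  expect_equal(fit1$var_participant, fit2$var_participant, tolerance = 1e-10)
})

test_that("fit_lmm flags rank deficiency with the offending columns", {
  d <- make_single(41)
  d$x1 <- 0
  d$x2 <- 0
  spec <- build_design(make_single(41), "single")
  expect_error(fit_lmm(spec, d), "x1")
})

test_that("mean recovery and CI coverage at trial scale (n = 24)", {
  reps <- 500
  hits <- logical(reps)
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- make_single(5000 + r, effect_c = 5, effect_nc = 0,
      sd_participant = 8, sd_residual = 6
    )
    fit <- fit_lmm(build_design(d, "single"), d)
    co <- fit$coefficients[fit$coefficients$term == "conditionC", ]
    est[r] <- co$estimate
    hits[r] <- co$ci_low <= 5 && 5 <= co$ci_high
  }
  expect_lt(abs(mean(est) - 5), 0.25)
  expect_gte(mean(hits), 0.92)
  expect_lte(mean(hits), 0.98)
})

test_that("direct AR1 REML agrees with the nlme corAR1 oracle", {
  d <- simulate_crossover_trial(one_vas_config(61, phi = 0.6))$data
  spec <- build_design(d, "repeated", outcome = "energy")
  fit <- fit_vas_lmm(spec, d)
  expect_false(fit$fallback)

  dd <- crossforce:::design_factors(d, "repeated")
  dd$tp <- as.integer(as.character(dd$timepoint))
  oracle <- nlme::lme(spec$fixed,
    random = ~ 1 | participant_id, data = dd, method = "REML",
    correlation = nlme::corAR1(form = ~ tp | participant_id / condition)
  )
  expect_equal(fit$coefficients$estimate, unname(nlme::fixef(oracle)),
    tolerance = 1e-3
  )
  phi_oracle <- as.numeric(coef(oracle$modelStruct$corStruct,
    unconstrained = FALSE
  ))
  expect_equal(fit$phi, phi_oracle, tolerance = 0.02)
  expect_equal(
    fit$var_residual, oracle$sigma^2,
    tolerance = 0.02 * oracle$sigma^2
  )
})

test_that("AR1 and independent fits agree when phi = 0", {
  d <- simulate_crossover_trial(one_vas_config(62, phi = 0))$data
  spec_ar1 <- build_design(d, "repeated", outcome = "energy")
  spec_ind <- build_design(d, "repeated",
    outcome = "energy", correlation = "independent"
  )
  f1 <- fit_vas_lmm(spec_ar1, d)
  f0 <- fit_vas_lmm(spec_ind, d)
  rms <- sqrt(mean((f1$coefficients$estimate - f0$coefficients$estimate)^2))
  scale <- sqrt(mean(f0$coefficients$estimate^2))
  expect_lt(rms / scale, 0.01)
})

test_that("returned AR1 estimate is a local REML optimum", {
  d <- simulate_crossover_trial(one_vas_config(63, phi = 0.5))$data
  fit <- fit_vas_lmm(build_design(d, "repeated", outcome = "energy"), d)
  at_opt <- reml_criterion(fit, fit$var_participant, fit$var_residual, fit$phi)
  expect_equal(at_opt, fit$reml_neg2, tolerance = 1e-6)
  set.seed(99)
  for (i in 1:100) {
    vb <- fit$var_participant * exp(rnorm(1, 0, 0.2))
    ve <- fit$var_residual * exp(rnorm(1, 0, 0.2))
    ph <- tanh(atanh(fit$phi) + rnorm(1, 0, 0.2))
    expect_gte(reml_criterion(fit, vb, ve, ph), at_opt - 1e-6)
  }
})

test_that("AR1 curvature failure falls back to independent residuals", {
  # near-unit-root series make the AR1 information degenerate
  d <- simulate_crossover_trial(one_vas_config(64, phi = 0))$data
  d <- d[order(d$participant_id, d$condition, d$timepoint), ]
  set.seed(4)
  walk <- ave(rnorm(nrow(d), 0, 5), paste(d$participant_id, d$condition),
    FUN = cumsum
  )
  d$value <- 50 + walk
  fit <- fit_vas_lmm(build_design(d, "repeated", outcome = "energy"), d)
  if (fit$fallback) {
    expect_match(fit$method, "fallback")
    expect_true(is.na(fit$phi))
  } else {
    succeed("AR1 fit survived the near-degenerate series")
  }
  # an explicit failure mode: every participant x condition series has a
  # single timepoint, so the AR1 coefficient is unidentifiable
  spec <- build_design(d, "repeated", outcome = "energy")
  d1 <- d[(d$condition == "P" & d$timepoint == 1) |
    (d$condition == "NC" & d$timepoint == 2) |
    (d$condition == "C" & d$timepoint == 3), ]
  expect_error(fit_vas_lmm(spec, d1), "unidentifiable")
})

test_that("marginal and conditional R2 follow the variance-ratio formula", {
  r2 <- nakagawa_r2_components(2, 1, 1)
  expect_equal(r2$marginal, 0.5)
  expect_equal(r2$conditional, 0.75)

  expect_equal(nakagawa_r2_components(0, 1, 1)$marginal, 0)
  lim <- nakagawa_r2_components(3, 1e-12, 1e-12)
  expect_equal(lim$marginal, 1, tolerance = 1e-9)
  expect_error(nakagawa_r2_components(0, 0, 0), "zero total variance")

  d <- make_single(71)
  fit <- fit_lmm(build_design(d, "single"), d)
  r2f <- nakagawa_r2(fit)
  expect_gte(r2f$marginal, 0)
  expect_lte(r2f$marginal, r2f$conditional)
  expect_lte(r2f$conditional, 1)
  expect_equal(
    r2f$marginal,
    fit$var_fixed / (fit$var_fixed + fit$var_participant + fit$var_residual)
  )
})

test_that("coefficient summaries carry inclusive significance stars", {
  expect_equal(significance_stars(c(0.01, 0.05, 0.001, 0.049, 0.2)),
    c("**", "*", "***", "*", "")
  )
  d <- make_single(81, effect_c = 20, sd_participant = 2, sd_residual = 2)
  fit <- fit_lmm(build_design(d, "single"), d)
  tab <- summarize_fit(fit)
  expect_true(all(c("term", "b", "ci_low", "ci_high", "p", "stars") %in% names(tab)))
  expect_true(all(tab$ci_low <= tab$b & tab$b <= tab$ci_high))
  row_c <- tab[tab$term == "conditionC", ]
  expect_equal(row_c$stars, "***")
  forest <- summarize_fit(fit, style = "forest_values")
  expect_setequal(names(forest), c("term", "b", "ci_low", "ci_high", "p", "stars"))

  empty <- fit
  empty$coefficients <- fit$coefficients[0, ]
  expect_equal(nrow(summarize_fit(empty)), 0)
})
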