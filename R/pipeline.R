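#' Round half away from zero
#'
#' Percentage-style rounding where `.05` rounds up (e.g. `58.35 -> 58.4`),
#' unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Blinding-efficacy summary
#'
#' Per-condition correct-identification rates from end-of-visit guesses: each
#' participant reports, once per condition received, which condition they
#' believe was provided. Percentages use one decimal, rounding half up.
#'
#' @param guesses Data.frame with `participant_id`, `condition` (the
#'   condition actually received) and `guess` (the reported condition).
#' @return Data.frame with `condition`, `n`, `n_correct`, `pct_correct`.
#' @export
#' @examples
#' g <- data.frame(
#'   participant_id = sprintf("P%02d", 1:24),
#'   condition = "C",
#'   guess = rep(c("C", "NC"), c(14, 10))
#' )
#' blinding_efficacy(g)
blinding_efficacy <- function(guesses) {
  need <- c("participant_id", "condition", "guess")
  if (!all(need %in% names(guesses))) {
    stop("guesses need participant_id, condition, guess columns", call. = FALSE)
  }
  key <- paste(guesses$participant_id, guesses$condition)
  if (anyDuplicated(key)) {
    stop("duplicate guesses: one guess per participant per condition",
      call. = FALSE
    )
  }
  out <- do.call(rbind, lapply(unique(guesses$condition), function(cond) {
    sub <- guesses[guesses$condition == cond, , drop = FALSE]
    nc <- sum(sub$guess == cond)
    data.frame(
      condition = cond, n = nrow(sub), n_correct = nc,
      pct_correct = round_half_up(100 * nc / nrow(sub), 1),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Read / write a tidy trial table
#'
#' The on-disk dialect is a long CSV with columns
#' `participant,sex,sequence,visit,condition,timepoint,outcome,value`
#' (empty `timepoint` for single-value outcomes). Reading restores the
#' package's internal column names, recomputes `preceding_condition` from the
#' sequence, codes the carryover indicators and tags each row's kind.
#'
#' @param path CSV path.
#' @param data Trial table to write.
#' @return `read_trial_table()`: the trial table;
#'   `write_trial_table()`: `path`, invisibly.
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(participant = "participant_id")
  for (old in names(ren)) {
    if (old %in% names(df)) names(df)[names(df) == old] <- ren[[old]]
  }
  need <- c("participant_id", "sex", "sequence", "visit", "condition", "outcome", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("trial CSV lacks columns: %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  if (!"timepoint" %in% names(df)) df$timepoint <- NA_integer_
  seq_split <- strsplit(df$sequence, "-", fixed = TRUE)
  df$preceding_condition <- vapply(seq_len(nrow(df)), function(i) {
    v <- df$visit[i]
    if (v == 1) "none" else seq_split[[i]][v - 1]
  }, character(1))
  df <- code_carryover(df)
  df$kind <- ifelse(is.na(df$timepoint), "single", "repeated")
  df
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(data, path) {
  out <- data.frame(
    participant = data$participant_id, sex = data$sex,
    sequence = data$sequence, visit = data$visit,
    condition = data$condition, timepoint = data$timepoint,
    outcome = data$outcome, value = data$value
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Settings for an end-to-end run: either a simulation config or an input
#' trial-table CSV (exactly one), the outcomes to analyse, transform policy,
#' AR1 switch, imputation count and output directory.
#'
#' @param simulation A [simulation_config()], or `NULL` when reading a CSV.
#' @param input_csv Path to a trial-table CSV, or `NULL` when simulating.
#' @param outcomes Character vector of outcomes to analyse (default: all in
#'   the data).
#' @param transform_policy `"preset"` (apply the configured per-outcome
#'   transforms), `"residual"` (data-driven selection via
#'   [select_transform()]) or `"none"`.
#' @param ar1 Fit repeated outcomes with AR1 residual correlation
#'   (default `TRUE`; fallback to independent on interval failure).
#' @param m_imputations Imputations when missing values are present
#'   (default 100).
#' @param invalidation_rules Named list of predicates for
#'   [invalidate_records()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param seed Integer seed for imputation (defaults to the simulation seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_csv = NULL,
                            outcomes = NULL,
                            transform_policy = c("preset", "residual", "none"),
                            ar1 = TRUE,
                            m_imputations = 100,
                            invalidation_rules = list(),
                            out_dir = NULL,
                            seed = NULL) {
  if (is.null(simulation) == is.null(input_csv)) {
    stop("supply exactly one of simulation config or input_csv", call. = FALSE)
  }
  if (is.null(seed)) {
    if (is.null(simulation)) {
      stop("seed is mandatory when reading data from CSV", call. = FALSE)
    }
    seed <- simulation$seed
  }
  structure(
    list(
      simulation = simulation, input_csv = input_csv, outcomes = outcomes,
      transform_policy = match.arg(transform_policy), ar1 = ar1,
      m_imputations = m_imputations, invalidation_rules = invalidation_rules,
      out_dir = out_dir, seed = seed
    ),
    class = "pipeline_config"
  )
}

stage_error <- function(stage, outcome = NULL, parent = NULL) {
  where <- if (is.null(outcome)) stage else sprintf("%s [%s]", stage, outcome)
  stop(sprintf(
    "pipeline stage '%s' failed: %s", where,
    if (is.null(parent)) "unknown error" else conditionMessage(parent)
  ), call. = FALSE)
}

#' Run the full crossover analysis pipeline
#'
#' Sequences the analysis end to end: load or simulate the trial table,
#' invalidate flagged records, report and multiply-impute missing values,
#' select or apply normalizing transforms per outcome, fit the crossover
#' mixed model for every outcome (AR1 residuals for repeated outcomes, with
#' independent-residual fallback), pool across imputations, and write
#' coefficient tables, fit JSON, the missingness report and a run manifest.
#' The run is a pure function of config + seed: rerunning with the same
#' config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A run report: `data` (analysed table), `missingness`, `fits`
#'   (named list of `fit_result`), `transforms` (named list of transform
#'   records), `summaries` (coefficient tables), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  data <- tryCatch(
    {
      if (!is.null(config$simulation)) {
        simulate_crossover_trial(config$simulation)$data
      } else {
        read_trial_table(config$input_csv)
      }
    },
    error = function(e) stage_error("load", parent = e)
  )
  if (!is.null(config$simulation) && config$simulation$missing_rate > 0) {
    data <- inject_missingness(data,
      rate = config$simulation$missing_rate,
      seed = config$seed + 101L
    )
  }
  outcomes <- config$outcomes %||% unique(data$outcome)
  unknown <- setdiff(outcomes, unique(data$outcome))
  if (length(unknown)) {
    stage_error("fit", outcome = unknown[1],
      parent = simpleError(sprintf("unknown outcome '%s'", unknown[1]))
    )
  }
  inv <- tryCatch(
    invalidate_records(data, config$invalidation_rules),
    error = function(e) stage_error("invalidate", parent = e)
  )
  data <- inv$data
  miss_report <- missingness_report(
    data,
    removed = stats::setNames(
      lapply(inv$report$removed, `[[`, "rows"),
      vapply(inv$report$removed, `[[`, character(1), "reason")
    )
  )
  vas_names <- unique(data$outcome[data$kind == "repeated"])
  completed <- tryCatch(
    {
      if (anyNA(data$value)) {
        impute(data,
          m = config$m_imputations, seed = config$seed + 202L,
          bounds = c(0, 100), bounds_outcomes = vas_names
        )
      } else {
        list(data)
      }
    },
    error = function(e) stage_error("impute", parent = e)
  )
  presets <- if (!is.null(config$simulation)) {
    config$simulation$transform_presets
  } else {
    c(pf_iso = "log_x", rfd50 = "log_x", rfd_peak = "ordered_quantile")
  }
  fits <- list()
  transforms <- list()
  summaries <- list()
  for (oc in outcomes) {
    res <- tryCatch(
      fit_outcome(completed, oc, config, presets),
      error = function(e) stage_error("fit", outcome = oc, parent = e)
    )
    fits[[oc]] <- res$fit
    transforms[[oc]] <- res$record
    summaries[[oc]] <- summarize_fit(res$fit)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("crossforce")),
    seed = config$seed,
    seeds_consumed = list(
      assignment_and_outcomes = if (!is.null(config$simulation)) config$simulation$seed else NULL,
      missingness = if (!is.null(config$simulation)) config$seed + 101L else NULL,
      imputation = if (anyNA(data$value)) config$seed + 202L else NULL
    ),
    n_records = nrow(data),
    outcomes = outcomes,
    m_imputations = length(completed),
    transform_policy = config$transform_policy,
    transforms = lapply(transforms, function(r) r$kind %||% "identity"),
    ar1 = config$ar1,
    fallbacks = vapply(fits, function(f) isTRUE(f$fallback), logical(1))
  )
  report <- list(
    data = data, missingness = miss_report, fits = fits,
    transforms = transforms, summaries = summaries, manifest = manifest
  )
  if (!is.null(config$out_dir)) {
    write_run_outputs(report, config$out_dir)
  }
  report
}

# fit one outcome across the completed datasets, pooling when m > 1
fit_outcome <- function(completed, oc, config, presets) {
  kind <- unique(completed[[1]]$kind[completed[[1]]$outcome == oc])
  fit_one <- function(tab) {
    sub <- tab[tab$outcome == oc, , drop = FALSE]
    record <- new_transform_record("identity", list())
    if (config$transform_policy == "preset" && oc %in% names(presets)) {
      tfd <- if (presets[[oc]] == "log_x") {
        log_x_transform(sub$value)
      } else {
        ordered_quantile_transform(sub$value)
      }
      sub$value <- tfd$values
      record <- tfd$record
    } else if (config$transform_policy == "residual") {
      spec0 <- build_design(sub, kind, outcome = oc)
      resid_fn <- function(v) {
        s <- sub
        s$value <- v
        stats::residuals(stats::lm(
          stats::update(spec0$fixed, . ~ . + participant_id),
          design_factors(s, kind)
        ))
      }
      sel <- select_transform(resid_fn, sub$value)
      sub$value <- sel$values
      record <- sel$record
    }
    spec <- build_design(sub, kind,
      outcome = oc,
      correlation = if (kind == "repeated" && config$ar1) "ar1" else "independent"
    )
    fit <- if (kind == "repeated") fit_vas_lmm(spec, sub) else fit_lmm(spec, sub)
    list(fit = fit, record = record)
  }
  ones <- lapply(completed, fit_one)
  fit <- if (length(ones) > 1L) {
    pool_fits(lapply(ones, `[[`, "fit"))
  } else {
    ones[[1]]$fit
  }
  list(fit = fit, record = ones[[1]]$record)
}

# serialize the run: fits, summaries, missingness, manifest
write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (oc in names(report$fits)) {
    write_fit_result(report$fits[[oc]], file.path(out_dir, paste0("fit_", oc, ".json")))
    utils::write.csv(report$summaries[[oc]],
      file.path(out_dir, paste0("coefficients_", oc, ".csv")),
      row.names = FALSE
    )
    rec <- report$transforms[[oc]]
    if (!is.null(rec) && rec$kind != "identity") {
      write_transform_record(rec, file.path(out_dir, paste0("transform_", oc, ".json")))
    }
  }
  write_missingness_report(
    report$missingness, file.path(out_dir, "missingness.json")
  )
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
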