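#' Condition labels and sequences
#'
#' The three conditions are the caffeinated supplement (`C`), its
#' non-caffeinated formulation (`NC`) and placebo (`P`). With three
#' conditions there are six possible orders in which a participant can
#' complete the trial.
#'
#' @return `conditions()`: character vector `c("P", "NC", "C")` (placebo
#'   first, the model reference level). `condition_sequences()`: character
#'   vector of the 6 sequences as dash-joined strings.
#' @export
conditions <- function() c("P", "NC", "C")

#' @rdname conditions
#' @export
condition_sequences <- function() {
  perms <- list(
    c("C", "NC", "P"), c("C", "P", "NC"), c("NC", "C", "P"),
    c("NC", "P", "C"), c("P", "C", "NC"), c("P", "NC", "C")
  )
  vapply(perms, paste, character(1), collapse = "-")
}

#' Counterbalanced sequence assignment
#'
#' Assigns condition sequences to participants so that, within each sex, each
#' of the 6 sequences is used exactly `n_per_sex / 6` times. The order of
#' assignment is a seeded random permutation drawn separately for each sex,
#' mirroring randomization performed separately for females and males.
#'
#' @param n_per_sex Participants per sex; must be divisible by 6.
#' @param seed Integer seed making the assignment reproducible.
#' @return Data.frame with columns `participant_id` (`P01`, ...), `sex`
#'   (`female`/`male`) and `sequence` (e.g. `"P-C-NC"`). Females are numbered
#'   first.
#' @export
#' @examples
#' a <- generate_counterbalanced_assignment(12, seed = 1)
#' table(a$sex, a$sequence)
generate_counterbalanced_assignment <- function(n_per_sex, seed) {
  if (n_per_sex %% 6 != 0) {
    stop(sprintf(
      "n_per_sex must be divisible by 6 to balance the sequences (got %d)",
      n_per_sex
    ), call. = FALSE)
  }
  set.seed(seed)
  seqs <- condition_sequences()
  per_sex <- function(sex) {
    pool <- rep(seqs, each = n_per_sex / 6)
    data.frame(sex = sex, sequence = sample(pool), stringsAsFactors = FALSE)
  }
  out <- rbind(per_sex("female"), per_sex("male"))
  out$participant_id <- sprintf("P%02d", seq_len(nrow(out)))
  out[, c("participant_id", "sex", "sequence")]
}

#' Expand assignments into per-visit trial records
#'
#' One row per participant x visit, with the condition received at that visit
#' and the condition received at the preceding visit (`none` at visit 1).
#'
#' @param assignments Data.frame from
#'   [generate_counterbalanced_assignment()].
#' @return Data.frame with `participant_id`, `sex`, `sequence`, `visit`,
#'   `condition`, `preceding_condition`.
#' @export
assignment_records <- function(assignments) {
  stopifnot(all(c("participant_id", "sex", "sequence") %in% names(assignments)))
  rows <- lapply(seq_len(nrow(assignments)), function(i) {
    conds <- strsplit(assignments$sequence[i], "-", fixed = TRUE)[[1]]
    if (length(conds) != 3L || !setequal(conds, conditions())) {
      stop(sprintf(
        "sequence '%s' is not a permutation of P, NC, C",
        assignments$sequence[i]
      ), call. = FALSE)
    }
    data.frame(
      participant_id = assignments$participant_id[i],
      sex = assignments$sex[i],
      sequence = assignments$sequence[i],
      visit = 1:3,
      condition = conds,
      preceding_condition = c("none", conds[1:2]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Code crossover carryover indicators
#'
#' Adds the two coded carryover variables to trial records: `x1 = 1` when the
#' preceding condition was the caffeinated supplement (`C`), `x2 = 1` when it
#' was the non-caffeinated supplement (`NC`). First-period rows (no preceding
#' condition) and placebo-preceded rows are both coded `(0, 0)`, so placebo is
#' the carryover reference. Which indicator flags which active condition is a
#' labelling choice; inference is invariant to it.
#'
#' @param records Data.frame with a `preceding_condition` column
#'   (`none`, `P`, `NC` or `C`).
#' @return The records with `x1` and `x2` columns added (other fields
#'   unchanged).
#' @export
code_carryover <- function(records) {
  if (!"preceding_condition" %in% names(records)) {
    stop("records must carry a preceding_condition column", call. = FALSE)
  }
  known <- c("none", conditions())
  bad <- setdiff(unique(records$preceding_condition), known)
  if (length(bad)) {
    stop(sprintf(
      "unknown preceding condition label: %s", paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  records$x1 <- as.integer(records$preceding_condition == "C")
  records$x2 <- as.integer(records$preceding_condition == "NC")
  records
}

#' Build the crossover model design
#'
#' Constructs the fixed/random/covariance specification for an outcome. For a
#' single-value outcome the fixed-effects structure is
#' `Condition + Sex + Condition:Sex + Visit + X1 + X2`; repeated
#' (visual-analog-scale) outcomes add `Time` and its interactions with
#' condition and sex. Reference levels are placebo, female, visit 1 and
#' timepoint 1. The random structure is an intercept per participant, and
#' repeated outcomes declare an AR1 residual correlation within
#' participant x condition over timepoint.
#'
#' @param records Trial records with `condition`, `sex`, `visit`, `x1`, `x2`,
#'   a `value` column, and `timepoint` for repeated outcomes.
#' @param outcome_kind `"single"` or `"repeated"`.
#' @param outcome Optional outcome name carried in the spec.
#' @param correlation Residual correlation for repeated outcomes: `"ar1"`
#'   (default) or `"independent"`.
#' @return An object of class `model_spec` with the model formula, kind,
#'   reference levels and correlation structure.
#' @export
build_design <- function(records, outcome_kind = c("single", "repeated"),
                         outcome = "outcome",
                         correlation = if (outcome_kind[1] == "repeated") "ar1" else "independent") {
  outcome_kind <- match.arg(outcome_kind)
  needed <- c("participant_id", "sex", "visit", "condition", "x1", "x2")
  if (outcome_kind == "repeated") needed <- c(needed, "timepoint")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop(sprintf("records lack columns: %s", paste(miss, collapse = ", ")),
      call. = FALSE
    )
  }
  for (f in c("condition", "sex", "visit",
    if (outcome_kind == "repeated") "timepoint")) {
    if (length(unique(records[[f]])) < 2L) {
      stop(sprintf(
        "design error: factor '%s' has fewer than 2 observed levels", f
      ), call. = FALSE)
    }
  }
  fixed <- if (outcome_kind == "single") {
    value ~ condition * sex + visit + x1 + x2
  } else {
    value ~ condition * sex * timepoint + visit + x1 + x2
  }
  spec <- list(
    outcome = outcome,
    kind = outcome_kind,
    fixed = fixed,
    reference = list(
      condition = "P", sex = "female", visit = "1", timepoint = "1"
    ),
    random = "~1 | participant_id",
    correlation = match.arg(correlation, c("ar1", "independent")),
    transform = NULL
  )
  class(spec) <- "model_spec"
  # fail early on rank deficiency for complete data
  mm <- stats::model.matrix(fixed, design_factors(records, outcome_kind))
  if (qr(mm)$rank < ncol(mm)) {
    stop("design matrix is rank deficient for these records", call. = FALSE)
  }
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %s (%s): %s; random %s; residuals %s\n",
    x$outcome, x$kind, deparse(x$fixed), x$random, x$correlation
  ))
  invisible(x)
}

# coerce design columns to factors with the reference levels first
design_factors <- function(records, outcome_kind) {
  d <- records
  d$condition <- factor(d$condition, levels = conditions())
  d$sex <- factor(d$sex, levels = c("female", "male"))
  d$visit <- factor(d$visit, levels = sort(unique(as.integer(d$visit))))
  if (outcome_kind == "repeated") {
    d$timepoint <- factor(d$timepoint,
      levels = sort(unique(as.integer(d$timepoint)))
    )
  }
  if (!"value" %in% names(d)) d$value <- 0
  d
}
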