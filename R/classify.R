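# Per-trial strategy labelling, participant classification, and cohort
# preprocessing / tabulation.

cohort_answer_cols <- function() paste0("answer_t", 1:4)

cohort_schema <- function() {
  c("participant_id", "gender", "ethnicity_raw", "ethnicity_pooled",
    "response_mode", cohort_answer_cols())
}

#' Pool ethnicity into the three analysis groups
#'
#' The model distinguishes Caucasian, Chinese, and a pooled "Other" group;
#' any raw ethnicity other than the first two is mapped to `"Other"`.
#' Missing or empty values stay `NA`.
#'
#' @param x Character vector of raw ethnicity values.
#' @return Character vector over `c("Caucasian", "Chinese", "Other")`.
#' @export
pool_ethnicity <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA
  ifelse(is.na(x), NA,
         ifelse(x %in% c("Caucasian", "Chinese"), x, "Other"))
}

#' Label one quadrant answer with its response strategy
#'
#' Inverts the strategy-to-quadrant map of [predicted_quadrant()]: for a
#' given signed turn angle, each of the four quadrants is the prediction of
#' exactly one strategy, so every answer receives exactly one label.
#'
#' @param turn_angle Signed turn angle of the trial, degrees, with magnitude
#'   in (0, 135).
#' @param answer A quadrant code (see [quadrants()]).
#' @return A strategy label (see [strategies()]).
#' @examples
#' label_answer(-60, "BL")  # "turner"
#' label_answer(-60, "FR")  # "spinner"
#' @export
label_answer <- function(turn_angle, answer) {
  if (!is.character(answer) || length(answer) != 1L ||
      !(answer %in% quadrants())) {
    po_stop("`answer` must be one of FL, FR, BL, BR", "po_invalid_parameter")
  }
  map <- strategy_quadrant_map(turn_angle)
  setNames(names(map), map)[[answer]]
}

#' Classify a participant from trial labels
#'
#' A participant is classified as a user of a strategy when that label
#' appears in at least 75% of the trials -- with four trials, at least
#' `ceiling(0.75 * 4) = 3` of them. Participants whose labels never reach
#' the criterion are classified `"no-preference"`. With other trial counts
#' and thresholds at or below one half, two labels could reach the criterion
#' simultaneously; that tie is classified `"no-preference"` (conservative).
#'
#' @param labels Character vector of per-trial strategy labels.
#' @param threshold Consistency criterion as a fraction of trials.
#' @return A single classification (see [classifications()]).
#' @examples
#' classify_participant(c("turner", "turner", "turner", "non-turner"))
#' @export
classify_participant <- function(labels, threshold = 0.75) {
  if (length(labels) < 1L || !all(labels %in% strategies())) {
    po_stop("`labels` must be strategy labels", "po_invalid_parameter")
  }
  need <- ceiling(threshold * length(labels))
  counts <- table(factor(labels, levels = strategies()))
  winners <- names(counts)[counts >= need]
  if (length(winners) == 1L) winners else "no-preference"
}

# Per-trial label matrix for a cohort table (rows = participants,
# columns = trials), via the per-trial inverse quadrant map.
label_matrix <- function(cohort, trial_plan = default_trial_plan()) {
  cols <- cohort_answer_cols()[seq_along(trial_plan)]
  if (!all(cols %in% names(cohort))) {
    po_stop("cohort lacks answer columns", "po_invalid_parameter")
  }
  out <- matrix(NA_character_, nrow(cohort), length(trial_plan),
                dimnames = list(NULL, cols))
  for (j in seq_along(trial_plan)) {
    map <- strategy_quadrant_map(trial_plan[j])
    inv <- setNames(names(map), map)
    ans <- as.character(cohort[[cols[j]]])
    bad <- !is.na(ans) & !(ans %in% quadrants())
    if (any(bad)) {
      po_stop(sprintf("invalid answer code(s): %s",
                      paste(unique(ans[bad]), collapse = ", ")),
              "po_invalid_parameter")
    }
    out[, j] <- inv[ans]
  }
  out
}

#' Label and classify every participant in a cohort table
#'
#' `label_cohort()` returns the per-trial strategy labels as a character
#' matrix; `classify_cohort()` appends the participant-level `classification`
#' column obtained from the consistency criterion of
#' [classify_participant()].
#'
#' @param cohort A cohort data frame with columns `answer_t1` .. `answer_t4`
#'   holding quadrant codes.
#' @param trial_plan Signed turn angles of the trials, in trial order.
#' @param threshold Consistency criterion as a fraction of trials.
#' @return `label_cohort()`: a character matrix (participants x trials).
#'   `classify_cohort()`: the cohort with a `classification` column added.
#' @export
label_cohort <- function(cohort, trial_plan = default_trial_plan()) {
  label_matrix(cohort, trial_plan)
}

#' @rdname label_cohort
#' @export
classify_cohort <- function(cohort, trial_plan = default_trial_plan(),
                            threshold = 0.75) {
  labs <- label_matrix(cohort, trial_plan)
  need <- ceiling(threshold * ncol(labs))
  counts <- vapply(strategies(), function(s) rowSums(labs == s, na.rm = TRUE),
                   numeric(nrow(labs)))
  if (nrow(labs) == 1L) counts <- matrix(counts, nrow = 1L,
                                         dimnames = list(NULL, strategies()))
  meets <- counts >= need
  nwin <- rowSums(meets)
  cls <- rep("no-preference", nrow(labs))
  one <- nwin == 1L
  if (any(one)) {
    cls[one] <- strategies()[max.col(meets[one, , drop = FALSE],
                                     ties.method = "first")]
  }
  cohort$classification <- cls
  cohort
}

#' Preprocess a raw cohort table
#'
#' Applies the preprocessing pipeline in order: (1) drop participants with
#' missing gender, ethnicity, or any missing trial answer; (2) classify the
#' remaining participants by the consistency criterion; (3) drop participants
#' classified as spinners (retained nowhere in the modelling because of data
#' sparseness -- individual spinner *answers* within other participants are
#' kept). Surviving rows keep their original order, and the operation is
#' idempotent.
#'
#' @param cohort A cohort data frame with the columns of
#'   [read_cohort_csv()]. An `ethnicity_pooled` column is derived from
#'   `ethnicity_raw` via [pool_ethnicity()] when absent.
#' @param trial_plan Signed turn angles of the trials.
#' @param threshold Consistency criterion as a fraction of trials.
#' @return A list of class `"preprocessed_cohort"` with elements `cohort`
#'   (the analysis table, with `classification`), and the exclusion log
#'   `n_input`, `n_missing`, `n_spinner`, `n_final`.
#' @export
preprocess_cohort <- function(cohort, trial_plan = default_trial_plan(),
                              threshold = 0.75) {
  if (!"ethnicity_pooled" %in% names(cohort)) {
    if (!"ethnicity_raw" %in% names(cohort)) {
      po_stop("cohort needs an ethnicity_pooled or ethnicity_raw column",
              "po_invalid_parameter")
    }
    cohort$ethnicity_pooled <- pool_ethnicity(cohort$ethnicity_raw)
  }
  n_input <- nrow(cohort)
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  miss <- blank(cohort$gender) | blank(cohort$ethnicity_pooled)
  for (col in cohort_answer_cols()[seq_along(trial_plan)]) {
    miss <- miss | blank(cohort[[col]])
  }
  kept <- cohort[!miss, , drop = FALSE]
  n_missing <- n_input - nrow(kept)
  if (nrow(kept) == 0L) {
    po_stop("no participants remain after removing incomplete rows",
            "po_empty_cohort")
  }
  kept <- classify_cohort(kept, trial_plan, threshold)
  spin <- kept$classification == "spinner"
  out <- kept[!spin, , drop = FALSE]
  n_spinner <- sum(spin)
  if (nrow(out) == 0L) {
    po_stop("no participants remain after excluding spinners",
            "po_empty_cohort")
  }
  structure(list(cohort = out, n_input = n_input, n_missing = n_missing,
                 n_spinner = n_spinner, n_final = nrow(out)),
            class = "preprocessed_cohort")
}

#' @export
print.preprocessed_cohort <- function(x, ...) {
  cat(sprintf(
    "<preprocessed_cohort> %d -> %d analysed (%d incomplete, %d spinner-classified removed)\n",
    x$n_input, x$n_final, x$n_missing, x$n_spinner))
  print(table(x$cohort$classification))
  invisible(x)
}

#' Per-trial and pooled answer-label frequencies
#'
#' Tabulates the strategy labels of every trial answer: counts and
#' proportions per trial, and pooled over all trials. Proportions are exact
#' ratios of counts, so each trial's proportions and the pooled proportions
#' sum to 1.
#'
#' @param cohort A cohort data frame with answer columns.
#' @param trial_plan Signed turn angles of the trials.
#' @return A list of class `"answer_frequencies"`: `counts` (trials x
#'   strategies), `proportions` (same shape), `pooled_counts` and `pooled`
#'   (named vectors over strategies).
#' @export
answer_frequencies <- function(cohort, trial_plan = default_trial_plan()) {
  labs <- label_matrix(cohort, trial_plan)
  counts <- t(vapply(seq_len(ncol(labs)), function(j) {
    table(factor(labs[, j], levels = strategies()))
  }, numeric(length(strategies()))))
  dimnames(counts) <- list(paste0("trial_", seq_len(ncol(labs))), strategies())
  pooled_counts <- colSums(counts)
  structure(list(counts = counts,
                 proportions = counts / rowSums(counts),
                 pooled_counts = pooled_counts,
                 pooled = pooled_counts / sum(pooled_counts)),
            class = "answer_frequencies")
}

#' @export
print.answer_frequencies <- function(x, ...) {
  cat("<answer_frequencies> pooled shares:\n")
  print(round(x$pooled, 4))
  invisible(x)
}

#' Trial-to-trial answer-label transitions
#'
#' Counts, for each pair of consecutive trials, how many participants moved
#' from giving one answer type to another. Every participant contributes one
#' transition per trial pair, so each slice sums to the number of
#' participants. Cells below `min_count` are flagged as suppressed for
#' display (small-cell noise) but still returned.
#'
#' @param cohort A cohort data frame with answer columns.
#' @param trial_plan Signed turn angles of the trials.
#' @param min_count Display cutoff; cells below it are flagged.
#' @return A `from x to x pair` count array with a logical `"suppressed"`
#'   attribute of the same shape.
#' @export
transition_counts <- function(cohort, trial_plan = default_trial_plan(),
                              min_count = 5) {
  labs <- label_matrix(cohort, trial_plan)
  np <- ncol(labs) - 1L
  arr <- array(0, dim = c(length(strategies()), length(strategies()), np),
               dimnames = list(from = strategies(), to = strategies(),
                               pair = paste0("t", seq_len(np), "-t",
                                             seq_len(np) + 1L)))
  for (j in seq_len(np)) {
    arr[, , j] <- table(factor(labs[, j], levels = strategies()),
                        factor(labs[, j + 1L], levels = strategies()))
  }
  attr(arr, "suppressed") <- arr < min_count
  arr
}

#' Share of a classification group ever giving a particular answer label
#'
#' Within the participants holding a given classification, the fraction
#' whose four trial labels include `label` at least once -- e.g. how many of
#' the no-preference participants gave at least one turner answer.
#'
#' @param cohort A classified cohort (see [classify_cohort()]).
#' @param trial_plan Signed turn angles of the trials.
#' @param classification Classification group to condition on.
#' @param label Strategy label to look for.
#' @return A list with `n_group`, `n_with`, and `fraction`.
#' @export
fraction_with_answer <- function(cohort, trial_plan = default_trial_plan(),
                                 classification = "no-preference",
                                 label = "turner") {
  if (!"classification" %in% names(cohort)) {
    cohort <- classify_cohort(cohort, trial_plan)
  }
  grp <- cohort$classification == classification
  labs <- label_matrix(cohort[grp, , drop = FALSE], trial_plan)
  has <- rowSums(labs == label, na.rm = TRUE) > 0
  list(n_group = sum(grp), n_with = sum(has),
       fraction = if (sum(grp) > 0) mean(has) else NA_real_)
}

#' Read or write a cohort CSV
#'
#' Cohort files are UTF-8, comma-separated with a header row and columns
#' `participant_id, gender, ethnicity_raw, ethnicity_pooled, response_mode,
#' answer_t1..answer_t4`, where answers use the quadrant codes FL/FR/BL/BR.
#' Turn directions are part of the run configuration (the trial plan), not
#' of the answer sheet. On reading, a missing `ethnicity_pooled` column is
#' derived from `ethnicity_raw`.
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  needed <- setdiff(cohort_schema(), "ethnicity_pooled")
  if (!all(needed %in% names(cohort))) {
    po_stop(sprintf("cohort CSV lacks column(s): %s",
                    paste(setdiff(needed, names(cohort)), collapse = ", ")),
            "po_invalid_parameter")
  }
  if (!"ethnicity_pooled" %in% names(cohort)) {
    cohort$ethnicity_pooled <- pool_ethnicity(cohort$ethnicity_raw)
  }
  cohort
}

#' @rdname read_cohort_csv
#' @param cohort A cohort data frame holding at least the schema columns.
#' @export
write_cohort_csv <- function(cohort, path) {
  missing_cols <- setdiff(cohort_schema(), names(cohort))
  if (length(missing_cols)) {
    po_stop(sprintf("cohort lacks column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "po_invalid_parameter")
  }
  utils::write.csv(cohort[, cohort_schema()], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
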