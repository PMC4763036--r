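# Fixture builders: cohorts are constructed in code, never stored.

# A cohort row whose four answers follow one strategy consistently
# (or an explicit vector of per-trial answers).
make_row <- function(id, gender = "female", ethnicity = "Caucasian",
                     response_mode = "pictorial", strategy = "turner",
                     answers = NULL, trial_plan = default_trial_plan()) {
  if (is.null(answers)) {
    answers <- vapply(trial_plan, function(a) {
      strategy_quadrant_map(a)[[strategy]]
    }, character(1))
  }
  out <- data.frame(participant_id = id, gender = gender,
                    ethnicity_raw = ethnicity, ethnicity_pooled = ethnicity,
                    response_mode = response_mode,
                    stringsAsFactors = FALSE)
  for (j in seq_along(answers)) out[[paste0("answer_t", j)]] <- answers[j]
  out
}

make_cohort <- function(strategies_vec, ...) {
  do.call(rbind, lapply(seq_along(strategies_vec), function(i) {
    make_row(sprintf("P%04d", i), strategy = strategies_vec[i], ...)
  }))
}

# Per-trial answers of a strategy under the default trial plan.
strategy_answers <- function(strategy, trial_plan = default_trial_plan()) {
  vapply(trial_plan, function(a) strategy_quadrant_map(a)[[strategy]],
         character(1))
}

# A 507-row cohort: 501 complete rows (3 of them spinner-consistent) plus
# 6 rows with missing demographics or answers, mirroring the preprocessing
# counts of the study design (507 -> 501 -> 498).
make_fixture_507 <- function(seed = 42) {
  coh <- generate_cohort(generator_config(seed = seed))
  spin <- strategy_answers("spinner")
  for (i in 1:3) {
    coh[i, paste0("answer_t", 1:4)] <- as.list(spin)
  }
  incomplete <- rbind(
    make_row("M0001", gender = NA),
    make_row("M0002", gender = NA),
    make_row("M0003", ethnicity = NA),
    make_row("M0004", ethnicity = NA),
    make_row("M0005"), make_row("M0006"))
  incomplete$ethnicity_pooled[3:4] <- NA
  incomplete$answer_t2[5] <- NA
  incomplete$answer_t4[6] <- NA
  out <- rbind(coh[, cohort_schema_cols()], incomplete[, cohort_schema_cols()])
  rownames(out) <- NULL
  out
}

cohort_schema_cols <- function() {
  c("participant_id", "gender", "ethnicity_raw", "ethnicity_pooled",
    "response_mode", paste0("answer_t", 1:4))
}

# Exact probability that a latent user of `strategy` is classified as
# something else under the per-trial lapse model: enumerate all 4^4
# per-trial label patterns (per trial the own label has probability
# 1 - eps, each other label eps / 3).
exact_misclassification <- function(strategy, eps, n_trials = 4) {
  labs <- strategies()
  grids <- expand.grid(rep(list(labs), n_trials), stringsAsFactors = FALSE)
  p_one <- function(l) ifelse(l == strategy, 1 - eps, eps / 3)
  total <- 0
  for (i in seq_len(nrow(grids))) {
    pat <- unlist(grids[i, ], use.names = FALSE)
    pr <- prod(p_one(pat))
    if (classify_participant(pat) != strategy) total <- total + pr
  }
  total
}
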