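# Synthetic-cohort generator: latent classifications drawn from the
# multinomial model, emitted as quadrant answers through the trajectory
# geometry, with a uniform lapse process.

#' Subgroup cell sizes of the reference cohort
#'
#' Number of participants in each ethnicity x response-mode x gender cell of
#' the classroom sample the generator emulates (501 participants with
#' complete demographics). Gender within each cell is fixed at these counts
#' rather than redrawn, so generated cohorts are exactly sized.
#'
#' @return A data frame with columns `ethnicity`, `response_mode`, `gender`
#'   and `n` (12 rows).
#' @export
reference_cell_sizes <- function() {
  data.frame(
    ethnicity = rep(rep(c("Caucasian", "Chinese", "Other"), each = 2), 2),
    response_mode = rep(c("pictorial", "text"), each = 6),
    gender = rep(c("male", "female"), 6),
    n = c(62L, 41L, 58L, 56L, 47L, 49L,
          55L, 29L, 29L, 36L, 22L, 17L)
  )
}

#' Configuration of the synthetic-cohort generator
#'
#' @param cell_sizes Data frame of per-cell participant counts as in
#'   [reference_cell_sizes()] (the default).
#' @param coefficients Generating [coefficient_matrix()]; defaults to the
#'   reference estimates with extreme entries capped at magnitude 5
#'   ([cap_coefficients()]), since the raw quasi-separation values would
#'   create empty cells at realistic sample sizes.
#' @param lapse_rate Per-trial probability in `[0, 1]` that a
#'   strategy-consistent participant's answer is replaced by a uniformly
#'   random other quadrant. The default 0.05 produces occasional
#'   off-pattern answers (and hence realistic no-preference rates) without
#'   overwhelming the latent signal.
#' @param trial_plan Signed turn angles of the trials.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `"generator_config"`.
#' @export
generator_config <- function(cell_sizes = reference_cell_sizes(),
                             coefficients = cap_coefficients(reference_coefficients()),
                             lapse_rate = 0.05,
                             trial_plan = default_trial_plan(),
                             seed = 1L) {
  stopifnot(is.data.frame(cell_sizes),
            all(c("ethnicity", "response_mode", "gender", "n") %in%
                  names(cell_sizes)),
            inherits(coefficients, "coef_matrix"))
  if (any(cell_sizes$n < 0)) {
    po_stop("cell sizes must be non-negative", "po_invalid_parameter")
  }
  check_scalar_number(lapse_rate, "lapse_rate")
  if (lapse_rate < 0 || lapse_rate > 1) {
    po_stop("lapse_rate must lie in [0, 1]", "po_invalid_parameter")
  }
  check_scalar_number(seed, "seed")
  structure(list(cell_sizes = cell_sizes, coefficients = coefficients,
                 lapse_rate = lapse_rate, trial_plan = trial_plan,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic cohort
#'
#' For every participant a latent classification is drawn from
#' [strategy_probabilities()] at the participant's covariates. Participants
#' with a latent strategy answer that strategy's predicted quadrant
#' ([predicted_quadrant()]) on every trial, each answer independently
#' replaced by a uniformly random other quadrant with probability
#' `lapse_rate`. Latent no-preference participants emit a 2-2 split over two
#' distinct randomly chosen strategies in random trial order, which
#' guarantees the consistency criterion fails. With `lapse_rate = 0` the
#' classification of the generated answers therefore reproduces the latent
#' class exactly.
#'
#' @param config A [generator_config()].
#' @return A cohort data frame in the [read_cohort_csv()] schema, with the
#'   latent classes in attribute `"latent_class"` and the configuration in
#'   attribute `"config"`. For synthetic participants `ethnicity_raw` equals
#'   the pooled group.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cells <- config$cell_sizes
  if (sum(cells$n) == 0) {
    po_stop("cell sizes sum to zero", "po_empty_cohort")
  }
  set.seed(config$seed)
  plan <- config$trial_plan
  ntr <- length(plan)
  # predicted quadrant of each strategy on each trial
  qmap <- vapply(plan, function(a) strategy_quadrant_map(a),
                 character(length(strategies())))
  rownames(qmap) <- strategies()
  # the three lapse alternatives for each target quadrant
  others <- t(vapply(quadrants(), function(q) setdiff(quadrants(), q),
                     character(3)))
  splits <- rbind(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1),
                  c(2, 1, 1, 2), c(2, 1, 2, 1), c(2, 2, 1, 1))
  classes <- c(outcomes_nonbaseline(), "no-preference")

  pieces <- vector("list", nrow(cells))
  latents <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    n <- cells$n[i]
    if (n == 0) next
    p <- strategy_probabilities(cells$ethnicity[i], cells$response_mode[i],
                                cells$gender[i], config$coefficients)
    latent <- sample(classes, n, replace = TRUE, prob = p[classes])
    ans <- matrix(NA_character_, n, ntr)
    strat <- latent != "no-preference"
    if (any(strat)) {
      ans[strat, ] <- qmap[latent[strat], , drop = FALSE]
      if (config$lapse_rate > 0) {
        lapse <- matrix(runif(sum(strat) * ntr) < config$lapse_rate,
                        sum(strat), ntr)
        if (any(lapse)) {
          tgt <- ans[strat, , drop = FALSE][lapse]
          pick <- sample.int(3, length(tgt), replace = TRUE)
          sub <- ans[strat, , drop = FALSE]
          sub[lapse] <- others[cbind(match(tgt, quadrants()), pick)]
          ans[strat, ] <- sub
        }
      }
    }
    npr <- which(!strat)
    if (length(npr)) {
      first <- sample.int(4, length(npr), replace = TRUE)
      second <- (first + sample.int(3, length(npr), replace = TRUE) - 1L) %% 4L + 1L
      arrangement <- splits[sample.int(6, length(npr), replace = TRUE), ,
                            drop = FALSE]
      for (k in seq_along(npr)) {
        pair <- c(first[k], second[k])
        ans[npr[k], ] <- qmap[cbind(pair[arrangement[k, ]], seq_len(ntr))]
      }
    }
    df <- data.frame(gender = cells$gender[i],
                     ethnicity_raw = cells$ethnicity[i],
                     ethnicity_pooled = cells$ethnicity[i],
                     response_mode = cells$response_mode[i],
                     stringsAsFactors = FALSE)
    df <- df[rep(1, n), , drop = FALSE]
    colnames(ans) <- cohort_answer_cols()[seq_len(ntr)]
    pieces[[i]] <- cbind(df, as.data.frame(ans, stringsAsFactors = FALSE))
    latents[[i]] <- latent
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  rownames(out) <- NULL
  out <- cbind(participant_id = sprintf("S%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  attr(out, "latent_class") <- unlist(latents, use.names = FALSE)
  attr(out, "config") <- config
  out
}

#' Write generator metadata alongside a cohort CSV
#'
#' Records the seed, lapse rate, trial plan and cohort size of a generated
#' cohort in a sidecar JSON file, so a run can be replayed exactly.
#'
#' @param cohort A cohort returned by [generate_cohort()].
#' @param path Path of the metadata JSON file.
#' @export
write_generator_metadata <- function(cohort, path) {
  cfg <- attr(cohort, "config")
  if (is.null(cfg)) {
    po_stop("cohort carries no generator config", "po_invalid_parameter")
  }
  jsonlite::write_json(list(seed = cfg$seed, lapse_rate = cfg$lapse_rate,
                            trial_plan = cfg$trial_plan,
                            n_participants = nrow(cohort)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
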