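# End-to-end orchestration: generate-or-load cohort -> preprocess ->
# tabulate -> fit -> LR tests -> odds ratios -> bootstrap -> report bundle.

#' Configuration of an end-to-end analysis run
#'
#' Exactly one input source is used: a cohort CSV path, or a
#' [generator_config()] for a synthetic cohort (the default when neither is
#' given, seeded from `seed`).
#'
#' @param cohort_csv Optional path to a cohort CSV ([read_cohort_csv()]).
#' @param generator Optional [generator_config()].
#' @param trial_plan Signed turn angles of the trials.
#' @param threshold Consistency criterion for classification.
#' @param alpha Significance level for LR tests and Wald intervals.
#' @param lr_type Term-deletion scheme for [likelihood_ratio_tests()].
#' @param bootstrap_B Bootstrap replicates; `0` skips the bootstrap stage.
#' @param seed Integer master seed; every stochastic stage derives its seed
#'   from it, so a rerun with the same configuration reproduces every
#'   output bit for bit.
#' @param out_dir Optional output directory for the report bundle.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(cohort_csv = NULL, generator = NULL,
                       trial_plan = default_trial_plan(), threshold = 0.75,
                       alpha = 0.05, lr_type = "III", bootstrap_B = 10000,
                       seed = 1L, out_dir = NULL) {
  if (!is.null(cohort_csv) && !is.null(generator)) {
    po_stop("give either cohort_csv or generator, not both",
            "po_invalid_parameter")
  }
  check_scalar_number(seed, "seed")
  check_scalar_number(bootstrap_B, "bootstrap_B")
  if (is.null(cohort_csv) && is.null(generator)) {
    generator <- generator_config(trial_plan = trial_plan,
                                  seed = as.integer(seed))
  }
  if (!is.null(cohort_csv) && !file.exists(cohort_csv)) {
    po_stop(sprintf("cohort CSV not found: %s", cohort_csv),
            "po_invalid_parameter")
  }
  structure(list(cohort_csv = cohort_csv, generator = generator,
                 trial_plan = trial_plan, threshold = threshold,
                 alpha = alpha, lr_type = lr_type,
                 bootstrap_B = as.integer(bootstrap_B),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields map directly onto [run_config()] arguments; a `generator`
#' sub-object maps onto [generator_config()] (its `coefficients`, if given,
#' as a 3 x 12 matrix of rows non-turner, turner, non-mover).
#'
#' @param path Configuration file (`.yaml`, `.yml` or `.json`).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$generator)) {
    g <- raw$generator
    args <- list()
    if (!is.null(g$cell_sizes)) args$cell_sizes <- as.data.frame(g$cell_sizes)
    if (!is.null(g$coefficients)) {
      args$coefficients <- coefficient_matrix(
        matrix(unlist(g$coefficients), nrow = 3, byrow = TRUE))
    }
    for (nm in c("lapse_rate", "trial_plan", "seed")) {
      if (!is.null(g[[nm]])) args[[nm]] <- g[[nm]]
    }
    raw$generator <- do.call(generator_config, args)
  }
  keep <- intersect(names(raw), names(formals(run_config)))
  do.call(run_config, raw[keep])
}

stage_msg <- function(fmt, ...) {
  message(sprintf("[pointorigin %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort acquisition (load or generate), preprocessing
#' with exclusion logging, answer-frequency and transition tabulation,
#' multinomial fit with likelihood-ratio term tests and training accuracy,
#' the binary turner/non-turner fit, significant odds-ratio extraction, and
#' the naive and weighted bootstrap nulls with a comparison verdict. Every
#' stage is a pure function of the configuration and its derived seeds.
#'
#' When `out_dir` is set, the bundle is written there: `cohort.csv`,
#' `exclusions.json`, `classification.csv`, `answer_frequencies.csv`,
#' `transitions.csv`, `fit_summary.json`, `lr_tests.csv`,
#' `odds_ratios.csv`, `bootstrap_naive.json`, `bootstrap_weighted.json` and
#' a `manifest.json` recording seeds, counts and package version.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list of class `"po_run"` with every stage result
#'   and the manifest.
#' @export
run_analysis <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  manifest <- list(package = "pointorigin",
                   version = as.character(utils::packageVersion("pointorigin")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, trial_plan = config$trial_plan)

  if (!is.null(config$cohort_csv)) {
    stage_msg("loading cohort from %s", config$cohort_csv)
    cohort <- read_cohort_csv(config$cohort_csv)
    manifest$source <- config$cohort_csv
  } else {
    stage_msg("generating synthetic cohort (seed %d)", config$generator$seed)
    cohort <- generate_cohort(config$generator)
    manifest$source <- "synthetic"
    manifest$generator_seed <- config$generator$seed
    manifest$lapse_rate <- config$generator$lapse_rate
  }
  manifest$n_generated <- nrow(cohort)

  stage_msg("preprocessing %d participants", nrow(cohort))
  prep <- preprocess_cohort(cohort, config$trial_plan, config$threshold)
  manifest$exclusions <- list(missing = prep$n_missing,
                              spinner = prep$n_spinner,
                              analysed = prep$n_final)

  freqs <- answer_frequencies(prep$cohort, config$trial_plan)
  trans <- transition_counts(prep$cohort, config$trial_plan)

  stage_msg("fitting multinomial model (n = %d)", prep$n_final)
  fit <- fit_strategy_model(prep$cohort)
  lr <- likelihood_ratio_tests(fit, type = config$lr_type)
  acc <- training_accuracy(fit)
  binfit <- fit_binary_logistic(prep$cohort)
  lr_bin <- likelihood_ratio_tests(binfit, type = config$lr_type)
  manifest$model <- list(converged = fit$converged,
                         log_likelihood = fit$log_likelihood,
                         training_accuracy = acc)

  stage_msg("extracting significant odds ratios")
  ors <- significant_ors(fit, alpha = config$alpha)
  manifest$n_significant_ors <- nrow(ors)

  boot <- NULL
  if (config$bootstrap_B > 0) {
    stage_msg("bootstrap nulls (B = %d)", config$bootstrap_B)
    observed <- prep$cohort$classification
    boot <- list(
      naive = null_accuracy(observed, "naive", config$bootstrap_B,
                            seed = config$seed + 104729L),
      weighted = null_accuracy(observed, "weighted", config$bootstrap_B,
                               seed = config$seed + 224737L))
    boot$verdict_naive <- compare_to_model(boot$naive, acc)
    boot$verdict_weighted <- compare_to_model(boot$weighted, acc)
    manifest$bootstrap <- list(
      B = config$bootstrap_B,
      naive_ci = boot$naive$ci, weighted_ci = boot$weighted$ci,
      verdict_naive = boot$verdict_naive$verdict,
      verdict_weighted = boot$verdict_weighted$verdict)
  } else {
    manifest$bootstrap <- "skipped"
  }

  result <- structure(list(cohort = cohort, preprocessed = prep,
                           answer_frequencies = freqs, transitions = trans,
                           fit = fit, lr_tests = lr,
                           training_accuracy = acc, binary_fit = binfit,
                           lr_tests_binary = lr_bin, odds_ratios = ors,
                           bootstrap = boot, manifest = manifest,
                           config = config),
                      class = "po_run")
  if (!is.null(out_dir)) write_run_bundle(result, out_dir)
  invisible(result)
}

write_run_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_cohort_csv(result$cohort, p("cohort.csv"))
  jsonlite::write_json(result$manifest$exclusions, p("exclusions.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(result$preprocessed$cohort[, c("participant_id",
                                                  "classification")],
                   p("classification.csv"), row.names = FALSE)
  freqs <- result$answer_frequencies
  utils::write.csv(data.frame(trial = rownames(freqs$proportions),
                              freqs$proportions, check.names = FALSE),
                   p("answer_frequencies.csv"), row.names = FALSE)
  tr <- result$transitions
  long <- expand.grid(from = dimnames(tr)$from, to = dimnames(tr)$to,
                      pair = dimnames(tr)$pair, stringsAsFactors = FALSE)
  long$count <- as.vector(tr)
  long$suppressed <- as.vector(attr(tr, "suppressed"))
  utils::write.csv(long, p("transitions.csv"), row.names = FALSE)
  write_fit_json(result$fit, p("fit_summary.json"), result$lr_tests)
  utils::write.csv(result$lr_tests, p("lr_tests.csv"), row.names = FALSE)
  utils::write.csv(result$odds_ratios, p("odds_ratios.csv"),
                   row.names = FALSE)
  if (!is.null(result$bootstrap)) {
    write_null_accuracy_json(result$bootstrap$naive, p("bootstrap_naive.json"))
    write_null_accuracy_json(result$bootstrap$weighted,
                             p("bootstrap_weighted.json"))
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.po_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<po_run> %s cohort: %d -> %d analysed (%d incomplete, %d spinner)\n",
              m$source, m$n_generated, m$exclusions$analysed,
              m$exclusions$missing, m$exclusions$spinner))
  cat(sprintf("  training accuracy %.3f | %d significant ORs\n",
              x$training_accuracy, nrow(x$odds_ratios)))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  null accuracy: naive [%.3f, %.3f] %s | weighted [%.3f, %.3f] %s\n",
                x$bootstrap$naive$ci[1], x$bootstrap$naive$ci[2],
                x$bootstrap$verdict_naive$verdict,
                x$bootstrap$weighted$ci[1], x$bootstrap$weighted$ci[2],
                x$bootstrap$verdict_weighted$verdict))
  }
  invisible(x)
}
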