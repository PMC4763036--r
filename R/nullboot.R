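# Bootstrap null distribution of classification accuracy for random
# classifiers, with percentile confidence intervals.

#' Bootstrap null accuracy of a random classifier
#'
#' Holds the observed participant classifications fixed and, in each of `B`
#' replicates, assigns every participant a random predicted class --
#' uniformly over the class set (`mode = "naive"`) or with probabilities
#' equal to the observed class frequencies (`mode = "weighted"`) -- then
#' scores the accuracy of that random prediction. The percentile interval
#' spans the middle 95% (or `1 - alpha`) of the replicate accuracies.
#'
#' As `B` grows, the naive mean accuracy approaches `1/K` (25% for the four
#' analysis classes -- the conventional chance level) and the weighted mean
#' approaches `sum(p^2)` where `p` is the observed class distribution.
#'
#' @param observed Character or factor vector of observed classifications,
#'   drawn from `class_set`.
#' @param mode `"naive"` or `"weighted"`.
#' @param B Number of bootstrap replicates; below 100 the percentiles are
#'   unstable and a warning is raised.
#' @param seed Optional integer seed; results are bit-reproducible from it.
#' @param class_set Class levels of the null; defaults to the four analysis
#'   classes (spinners are excluded before analysis).
#' @param alpha Tail mass outside the percentile interval.
#' @return An object of class `"null_accuracy"`: `mode`, `replicates`,
#'   `accuracies`, `ci` (2.5th and 97.5th percentiles), `mean`, `seed`,
#'   `n_participants`, `class_set`.
#' @export
null_accuracy <- function(observed, mode = c("naive", "weighted"), B = 10000,
                          seed = NULL, class_set = analysis_classes(),
                          alpha = 0.05) {
  mode <- match.arg(mode)
  observed <- as.character(observed)
  if (length(observed) == 0L) {
    po_stop("`observed` is empty", "po_empty_cohort")
  }
  if (!all(observed %in% class_set)) {
    po_stop("observed labels outside the class set", "po_invalid_parameter")
  }
  check_scalar_number(B, "B")
  if (B < 1) po_stop("B must be at least 1", "po_invalid_parameter")
  if (B < 100) {
    warning("B < 100: percentile interval will be unstable", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(observed)
  k <- length(class_set)
  prob <- if (mode == "naive") rep(1 / k, k)
          else as.vector(table(factor(observed, class_set))) / n
  oi <- match(observed, class_set)
  draws <- matrix(sample.int(k, n * as.integer(B), replace = TRUE, prob = prob),
                  nrow = B)
  acc <- rowMeans(draws == matrix(oi, B, n, byrow = TRUE))
  structure(list(mode = mode, replicates = as.integer(B), accuracies = acc,
                 ci = unname(quantile(acc, c(alpha / 2, 1 - alpha / 2))),
                 mean = mean(acc), seed = seed, n_participants = n,
                 class_set = class_set),
            class = "null_accuracy")
}

#' @export
print.null_accuracy <- function(x, ...) {
  cat(sprintf(
    "<null_accuracy> %s, B = %d, n = %d\n  mean %.4f, 95%% percentile interval [%.4f, %.4f]\n",
    x$mode, x$replicates, x$n_participants, x$mean, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Compare a model's accuracy with a bootstrap null interval
#'
#' States whether the model accuracy falls strictly above the upper
#' percentile bound of the null distribution (better than chance), strictly
#' below the lower bound (flagged separately), or inside the interval. The
#' boundary convention is strict: accuracy exactly equal to a bound is not
#' outside.
#'
#' @param result A [null_accuracy()] result.
#' @param model_accuracy Model accuracy as a proportion.
#' @return A list of class `"null_comparison"`: `verdict` (one of
#'   `"outside-high"`, `"outside-low"`, `"inside"`), `exceeds_upper`,
#'   `ci` and `model_accuracy`.
#' @export
compare_to_model <- function(result, model_accuracy) {
  stopifnot(inherits(result, "null_accuracy"))
  check_scalar_number(model_accuracy, "model_accuracy")
  verdict <- if (model_accuracy > result$ci[2]) "outside-high"
             else if (model_accuracy < result$ci[1]) "outside-low"
             else "inside"
  structure(list(verdict = verdict,
                 exceeds_upper = model_accuracy > result$ci[2],
                 ci = result$ci, model_accuracy = model_accuracy,
                 mode = result$mode),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("<null_comparison> model %.4f vs %s null [%.4f, %.4f]: %s\n",
              x$model_accuracy, x$mode, x$ci[1], x$ci[2], x$verdict))
  invisible(x)
}

#' Write a bootstrap result as JSON (and optionally the accuracy vector)
#'
#' @param result A [null_accuracy()] result.
#' @param path JSON output path.
#' @param accuracies_csv Optional CSV path for the full replicate vector.
#' @export
write_null_accuracy_json <- function(result, path, accuracies_csv = NULL) {
  stopifnot(inherits(result, "null_accuracy"))
  jsonlite::write_json(
    list(mode = result$mode, replicates = result$replicates,
         seed = result$seed, n_participants = result$n_participants,
         mean = result$mean, ci_low = result$ci[1], ci_high = result$ci[2]),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(accuracies_csv)) {
    utils::write.csv(data.frame(accuracy = result$accuracies),
                     accuracies_csv, row.names = FALSE)
  }
  invisible(path)
}
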