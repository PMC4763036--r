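# Pairwise odds ratios from the multinomial coefficients, under every
# baseline rotation, with Wald intervals and the reporting filters.

or_outcomes <- function(fit = NULL) {
  if (!is.null(fit) && isTRUE(fit$binary)) c("non-turner", "turner")
  else analysis_classes()
}

# Linear-predictor offset of outcome k under design-row difference dx;
# the baseline outcome has all-zero coefficients.
lp_delta <- function(coefficients, outcome, dx) {
  if (outcome == "no-preference") 0 else sum(coefficients[outcome, ] * dx)
}

#' Odds ratio between two outcomes for a factor contrast
#'
#' The odds of classification `target` relative to `baseline` change, when
#' the contrast factor moves from `level_b` to `level_a` with the remaining
#' factors held at `profile`, by
#' `OR = exp[(eta_target(a) - eta_target(b)) - (eta_baseline(a) - eta_baseline(b))]`
#' where `eta_k` is outcome k's linear predictor (identically zero for the
#' model's reference outcome no-preference). This equals the ratio of
#' softmax-probability odds at the two covariate profiles, and is invariant
#' to which baseline rotation parametrizes the model.
#'
#' When `coefficients` is a fitted `"strategy_fit"`, a Wald interval for
#' the log odds ratio is attached: delta-method over the full coefficient
#' covariance when available, otherwise (printed coefficients) the
#' independent-SE approximation `sqrt(sum (c_i SE_i)^2)`, marked
#' approximate.
#'
#' @param coefficients A [coefficient_matrix()] or a `"strategy_fit"`.
#' @param target,baseline Outcome classes being compared (see
#'   [classifications()]; `"no-preference"` is the model's zero-coefficient
#'   reference outcome).
#' @param factor One of `"ethnicity"`, `"response_mode"`, `"gender"`.
#' @param level_a,level_b Levels of `factor` being contrasted (odds of
#'   `target` at `level_a` relative to `level_b`).
#' @param profile Named list fixing every factor not in the contrast, e.g.
#'   `list(gender = "male", response_mode = "pictorial")`.
#' @param conf_level Confidence level of the Wald interval.
#' @return An object of class `"or_record"`: `or`, `log_or`, the contrast
#'   description, and (for fits) `se`, `ci`, `significant`, `approx`.
#' @examples
#' odds_ratio(reference_coefficients(), "turner", "non-turner",
#'            "gender", "male", "female",
#'            profile = list(ethnicity = "Caucasian",
#'                           response_mode = "pictorial"))
#' @export
odds_ratio <- function(coefficients, target, baseline, factor, level_a,
                       level_b, profile, conf_level = 0.95) {
  fit <- NULL
  if (inherits(coefficients, "strategy_fit")) {
    fit <- coefficients
    coefficients <- fit$coefficients
  }
  stopifnot(inherits(coefficients, "coef_matrix") ||
              (!is.null(fit) && is.matrix(coefficients)))
  ok_outcomes <- or_outcomes(fit)
  if (!(target %in% ok_outcomes) || !(baseline %in% ok_outcomes)) {
    po_stop("target and baseline must be analysis classes",
            "po_invalid_contrast")
  }
  lv <- factor_levels()
  if (!(factor %in% names(lv))) {
    po_stop(sprintf("unknown factor '%s'", factor), "po_invalid_contrast")
  }
  if (!(level_a %in% lv[[factor]]) || !(level_b %in% lv[[factor]])) {
    po_stop(sprintf("level(s) not in design for factor '%s'", factor),
            "po_invalid_contrast")
  }
  need <- setdiff(names(lv), factor)
  if (!all(need %in% names(profile))) {
    po_stop(sprintf("profile must fix factor(s): %s",
                    paste(setdiff(need, names(profile)), collapse = ", ")),
            "po_invalid_contrast")
  }
  pa <- pb <- profile
  pa[[factor]] <- level_a
  pb[[factor]] <- level_b
  xa <- design_row(pa$ethnicity, pa$response_mode, pa$gender)
  xb <- design_row(pb$ethnicity, pb$response_mode, pb$gender)
  dx <- xa - xb
  base_outcome <- if (!is.null(fit) && fit$binary) "non-turner" else "no-preference"
  dl <- function(k) {
    if (k == base_outcome) 0 else sum(coefficients[k, ] * dx)
  }
  log_or <- dl(target) - dl(baseline)
  rec <- list(target = target, baseline = baseline, factor = factor,
              level_a = level_a, level_b = level_b,
              profile = profile[need], log_or = log_or, or = exp(log_or))
  if (!is.null(fit) && (!is.null(fit$vcov) || !is.null(fit$standard_errors))) {
    w <- or_wald(fit, dx, target, baseline, base_outcome, conf_level)
    rec <- c(rec, w)
  }
  structure(rec, class = "or_record")
}

# Wald SE of the log OR: contrast weights +dx on the target outcome's
# coefficients and -dx on the baseline outcome's (zero for the model's
# reference outcome).
or_wald <- function(fit, dx, target, baseline, base_outcome, conf_level) {
  rows <- rownames(fit$coefficients)
  terms <- colnames(fit$coefficients)
  wt <- matrix(0, length(rows), length(terms), dimnames = list(rows, terms))
  if (target != base_outcome) wt[target, ] <- wt[target, ] + dx
  if (baseline != base_outcome) wt[baseline, ] <- wt[baseline, ] - dx
  if (!is.null(fit$vcov)) {
    nms <- as.vector(t(outer(rows, terms, paste, sep = ":")))
    cvec <- as.vector(t(wt))[match(rownames(fit$vcov), nms)]
    se <- sqrt(as.numeric(t(cvec) %*% fit$vcov %*% cvec))
    approx <- FALSE
  } else {
    se <- sqrt(sum((wt * fit$standard_errors)^2))
    approx <- TRUE
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  lo <- sum(wt * fit$coefficients) - z * se
  hi <- sum(wt * fit$coefficients) + z * se
  list(se = se, ci = c(exp(lo), exp(hi)),
       significant = (exp(lo) > 1) || (exp(hi) < 1), approx = approx)
}

#' @export
print.or_record <- function(x, ...) {
  prof <- paste(sprintf("%s=%s", names(x$profile), unlist(x$profile)),
                collapse = ", ")
  cat(sprintf("<or_record> %s vs %s | %s: %s vs %s | %s\n  OR = %.4g",
              x$target, x$baseline, x$factor, x$level_a, x$level_b, prof,
              x$or))
  if (!is.null(x$ci)) {
    cat(sprintf("  [%.4g, %.4g]%s%s", x$ci[1], x$ci[2],
                if (isTRUE(x$significant)) " *" else "",
                if (isTRUE(x$approx)) " (approx SE)" else ""))
  }
  cat("\n")
  invisible(x)
}

#' Enumerate all baseline rotations of the design
#'
#' Every combination of reference levels of the dummy-coded factors -- for
#' the default design, 3 (ethnicity) x 2 (response mode) x 2 (gender) = 12
#' parametrizations. Rotating the baseline rephrases the model without
#' changing it, so the odds ratio of any fixed contrast and profile is
#' identical under every rotation.
#'
#' @param design_spec Named list of factor levels; defaults to
#'   [factor_levels()].
#' @return A data frame with one row per reference-level combination.
#' @export
enumerate_rotations <- function(design_spec = factor_levels()) {
  out <- expand.grid(design_spec, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  rownames(out) <- NULL
  out
}

#' Extract all significant odds ratios
#'
#' Enumerates every ordered outcome pair, every ordered level pair of every
#' factor, and every profile of the remaining factors; computes each odds
#' ratio with its Wald interval ([odds_ratio()]); and applies the reporting
#' filters: keep records whose interval excludes 1, drop odds ratios below
#' `window[1]` or above `window[2]` (extreme values are artifacts of sparse
#' cells with huge intervals), and report only the greater-than-one
#' orientation of each reciprocal pair.
#'
#' @param fit A `"strategy_fit"` (fitted, or from [printed_fit()] -- the
#'   latter uses the approximate independent-SE intervals).
#' @param alpha Significance level of the Wald intervals.
#' @param window Inclusion window `c(low, high)` on the odds-ratio value.
#' @return A data frame with one row per retained record: outcome pair,
#'   contrast, profile columns, `or`, `ci_low`, `ci_high`, `se_log_or`,
#'   `approx`.
#' @export
significant_ors <- function(fit, alpha = 0.05, window = c(0.001, 100)) {
  stopifnot(inherits(fit, "strategy_fit"))
  if (is.null(fit$vcov) && is.null(fit$standard_errors)) {
    po_stop("fit carries neither covariance nor standard errors",
            "po_invalid_parameter")
  }
  if (is.null(fit$vcov)) {
    warning("no coefficient covariance: using independent-SE approximation for Wald intervals",
            call. = FALSE)
  }
  classes <- or_outcomes(fit)
  lv <- factor_levels()
  rows <- list()
  for (target in classes) for (baseline in setdiff(classes, target)) {
    for (f in names(lv)) {
      levs <- lv[[f]]
      pairs <- expand.grid(a = levs, b = levs, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, ]
      others <- setdiff(names(lv), f)
      profiles <- expand.grid(lv[others], stringsAsFactors = FALSE,
                              KEEP.OUT.ATTRS = FALSE)
      for (i in seq_len(nrow(pairs))) for (j in seq_len(nrow(profiles))) {
        rec <- suppressWarnings(odds_ratio(
          fit, target, baseline, f, pairs$a[i], pairs$b[i],
          profile = as.list(profiles[j, , drop = FALSE]),
          conf_level = 1 - alpha))
        if (!isTRUE(rec$significant)) next
        if (rec$or <= 1) next
        if (rec$or < window[1] || rec$or > window[2]) next
        row <- data.frame(target = target, baseline = baseline, factor = f,
                          level_a = pairs$a[i], level_b = pairs$b[i],
                          ethnicity = NA_character_,
                          response_mode = NA_character_,
                          gender = NA_character_,
                          or = rec$or, ci_low = rec$ci[1], ci_high = rec$ci[2],
                          se_log_or = rec$se, approx = rec$approx,
                          stringsAsFactors = FALSE)
        for (o in others) row[[o]] <- profiles[j, o]
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target = character(), baseline = character(),
               factor = character(), level_a = character(),
               level_b = character(), ethnicity = character(),
               response_mode = character(), gender = character(),
               or = numeric(), ci_low = numeric(), ci_high = numeric(),
               se_log_or = numeric(), approx = logical())
  out <- out[order(out$factor, -out$or), ]
  rownames(out) <- NULL
  out
}
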