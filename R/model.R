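# Multinomial and binary logistic modelling of participant classification
# on ethnicity, response mode and gender, with likelihood-ratio term tests.

model_formula <- function() {
  classification ~ ethnicity * response_mode * gender
}

# Validate a classified cohort and coerce its factors to canonical levels.
as_model_frame <- function(cohort, binary = FALSE) {
  if (!"classification" %in% names(cohort)) {
    po_stop("cohort has no classification column; run preprocess_cohort() or classify_cohort() first",
            "po_invalid_parameter")
  }
  lv <- factor_levels()
  if (binary) {
    cohort <- cohort[cohort$classification %in% c("non-turner", "turner"), ,
                     drop = FALSE]
    ylev <- c("non-turner", "turner")
  } else {
    if (any(cohort$classification == "spinner")) {
      po_stop("spinner-classified participants must be excluded before fitting",
              "po_invalid_parameter")
    }
    ylev <- analysis_classes()
  }
  bad <- !(cohort$classification %in% ylev)
  if (any(bad)) {
    po_stop(sprintf("unknown classification value(s): %s",
                    paste(unique(cohort$classification[bad]), collapse = ", ")),
            "po_invalid_parameter")
  }
  mf <- data.frame(
    classification = factor(cohort$classification, levels = ylev),
    ethnicity = factor(cohort$ethnicity_pooled, levels = lv$ethnicity),
    response_mode = factor(cohort$response_mode, levels = lv$response_mode),
    gender = factor(cohort$gender, levels = lv$gender))
  if (anyNA(mf)) {
    po_stop("cohort contains values outside the model's factor levels",
            "po_invalid_parameter")
  }
  tab <- table(mf$ethnicity, mf$response_mode, mf$gender)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    po_stop(sprintf("design is rank deficient: empty cell (%s, %s, %s)",
                    dimnames(tab)[[1]][empty[1]], dimnames(tab)[[2]][empty[2]],
                    dimnames(tab)[[3]][empty[3]]),
            "po_rank_deficiency")
  }
  mf
}

new_strategy_fit <- function(coefficients, standard_errors, vcov, ll, mf,
                             model, converged, binary) {
  structure(list(coefficients = coefficients,
                 standard_errors = standard_errors, vcov = vcov,
                 log_likelihood = ll, n_obs = nrow(mf) %||% 0L,
                 converged = converged, data = mf, model = model,
                 binary = binary, baseline = "no-preference"),
            class = "strategy_fit")
}

#' Fit the multinomial classification model
#'
#' Maximum-likelihood fit (via [nnet::multinom()]) of the softmax model of
#' [strategy_probabilities()]: participant classification (baseline
#' no-preference) on ethnicity, response mode, gender and all their
#' interactions, dummy coded against Caucasian / pictorial / female. The
#' optimizer is deterministic (zero start), so the fit is reproducible
#' given the data. Coefficients with standard errors above 10 trigger a
#' quasi-separation warning; non-convergence is flagged on the returned
#' object, not raised.
#'
#' @param cohort A classified cohort without spinner-classified rows (see
#'   [preprocess_cohort()]).
#' @param maxit Maximum optimizer iterations.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @return An object of class `"strategy_fit"` holding the fitted
#'   [coefficient_matrix()], standard errors, coefficient covariance,
#'   log-likelihood, data and convergence flag.
#' @export
fit_strategy_model <- function(cohort, maxit = 200, reltol = 1e-10) {
  mf <- as_model_frame(cohort)
  m <- nnet::multinom(model_formula(), data = mf, Hess = TRUE, trace = FALSE,
                      maxit = maxit, reltol = reltol)
  co <- coef(m)
  colnames(co) <- design_terms()[match(colnames(co), term_aliases())]
  co <- coefficient_matrix(co[outcomes_nonbaseline(), design_terms()])
  se <- summary(m)$standard.errors
  colnames(se) <- colnames(co)
  se <- se[outcomes_nonbaseline(), design_terms()]
  if (any(se > 10)) {
    warning("standard error(s) above 10: probable quasi-separation in some cell",
            call. = FALSE)
  }
  V <- tryCatch(vcov(m), error = function(e) NULL)
  if (!is.null(V)) {
    dimnames(V) <- list(canonical_vcov_names(rownames(V)),
                        canonical_vcov_names(colnames(V)))
  }
  new_strategy_fit(co, se, V, as.numeric(logLik(m)), mf, m,
                   converged = (m$convergence == 0), binary = FALSE)
}

# nnet names columns by R's factor dummy naming; identical here by
# construction, but mapped explicitly for safety.
term_aliases <- function() design_terms()

canonical_vcov_names <- function(nms) {
  for (o in outcomes_nonbaseline()) {
    pre <- paste0(o, ":")
    hit <- startsWith(nms, pre)
    nms[hit] <- paste0(pre, substring(nms[hit], nchar(pre) + 1))
  }
  nms
}

#' Fit the binary turner vs non-turner logistic model
#'
#' Restricts the cohort to the two dominant classes and fits a binomial
#' logit of turner (vs baseline non-turner) on the same dummy-coded design
#' as [fit_strategy_model()].
#'
#' @param cohort A classified cohort.
#' @return A `"strategy_fit"` with a single coefficient row `"turner"`.
#' @export
fit_binary_logistic <- function(cohort) {
  mf <- as_model_frame(cohort, binary = TRUE)
  if (length(unique(mf$classification)) < 2L) {
    po_stop("binary model needs both turner and non-turner participants",
            "po_rank_deficiency")
  }
  m <- stats::glm(classification ~ ethnicity * response_mode * gender,
                  family = binomial(), data = mf)
  co <- matrix(coef(m), nrow = 1,
               dimnames = list("turner", design_terms()))
  se <- matrix(sqrt(diag(vcov(m))), nrow = 1,
               dimnames = list("turner", design_terms()))
  V <- vcov(m)
  dimnames(V) <- list(paste0("turner:", design_terms()),
                      paste0("turner:", design_terms()))
  new_strategy_fit(co, se, V, as.numeric(logLik(m)), mf, m,
                   converged = m$converged, binary = TRUE)
}

# Deviance (-2 log-likelihood) of a multinomial or binomial fit on an
# explicit design-matrix subset; used for term-deletion tests.
refit_deviance <- function(fit, X) {
  y <- fit$data$classification
  if (fit$binary) {
    g <- stats::glm.fit(x = X, y = y == "turner", family = binomial())
    list(deviance = g$deviance, converged = g$converged)
  } else {
    m <- nnet::multinom(y ~ X - 1, data = list(y = y, X = X), trace = FALSE,
                        maxit = 200, reltol = 1e-10)
    list(deviance = m$deviance, converged = (m$convergence == 0))
  }
}

#' Likelihood-ratio tests of the model terms
#'
#' For each factor or interaction, twice the log-likelihood difference
#' between a richer and a poorer model, referred to a chi-square
#' distribution with degrees of freedom equal to the number of deleted
#' design columns times the number of modelled outcome contrasts (3 for the
#' multinomial model, 1 for the binary one).
#'
#' Two deletion schemes are offered. `type = "III"` (default) drops the
#' tested term from the otherwise complete model, leaving higher-order
#' terms that contain it in place; this produces one row per term against
#' the full fit. `type = "II"` is the classical hierarchical scheme: terms
#' containing the tested one are removed from both models before comparing.
#' With dummy coding, type III tests of main effects are evaluated at the
#' reference levels of the other factors.
#'
#' @param fit A `"strategy_fit"` from [fit_strategy_model()] or
#'   [fit_binary_logistic()].
#' @param terms Term labels to test (default: all seven).
#' @param type `"III"` or `"II"` (see Details).
#' @return A data frame with columns `term`, `lr_chi2`, `df`, `p` and
#'   `converged` (whether the reduced fit converged).
#' @export
likelihood_ratio_tests <- function(fit, terms = NULL, type = c("III", "II")) {
  stopifnot(inherits(fit, "strategy_fit"))
  type <- match.arg(type)
  if (is.null(fit$data)) {
    po_stop("likelihood-ratio tests need a fit with data (not printed coefficients)",
            "po_invalid_parameter")
  }
  if (!fit$converged) {
    warning("full model had not converged; LR statistics may be unreliable",
            call. = FALSE)
  }
  X <- model.matrix(~ ethnicity * response_mode * gender, fit$data)
  colnames(X) <- design_terms()[match(colnames(X), term_aliases())]
  asg <- attr(X, "assign")
  labels <- attr(terms(~ ethnicity * response_mode * gender), "term.labels")
  terms <- terms %||% labels
  bad <- setdiff(terms, labels)
  if (length(bad)) {
    po_stop(sprintf("unknown term(s): %s", paste(bad, collapse = ", ")),
            "po_invalid_parameter")
  }
  k_out <- if (fit$binary) 1L else length(outcomes_nonbaseline())
  contains <- function(t) {
    tv <- strsplit(t, ":", fixed = TRUE)[[1]]
    keep <- vapply(labels, function(u) {
      uv <- strsplit(u, ":", fixed = TRUE)[[1]]
      u != t && all(tv %in% uv)
    }, logical(1))
    labels[keep]
  }
  rows <- lapply(terms, function(t) {
    i <- match(t, labels)
    if (type == "III") {
      full_cols <- seq_len(ncol(X))
      red_cols <- which(asg != i)
      full_dev <- -2 * fit$log_likelihood
      full_conv <- TRUE
    } else {
      drop_up <- match(contains(t), labels)
      full_cols <- which(!(asg %in% drop_up))
      red_cols <- which(!(asg %in% c(i, drop_up)))
      f <- refit_deviance(fit, X[, full_cols, drop = FALSE])
      full_dev <- f$deviance
      full_conv <- f$converged
    }
    r <- refit_deviance(fit, X[, red_cols, drop = FALSE])
    df <- k_out * (length(full_cols) - length(red_cols))
    lr <- max(0, r$deviance - full_dev)
    data.frame(term = t, lr_chi2 = lr, df = df,
               p = pchisq(lr, df, lower.tail = FALSE),
               converged = r$converged && full_conv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Linear predictors (participants x non-baseline outcomes) of a fit or
# coefficient matrix on a classified cohort.
linear_predictors <- function(coefficients, mf) {
  X <- t(mapply(design_row, as.character(mf$ethnicity),
                as.character(mf$response_mode), as.character(mf$gender)))
  X %*% t(coefficients)
}

#' Training accuracy of a fitted model
#'
#' Fraction of participants whose highest-probability class under the model
#' equals their observed classification. For an intercept-only model this
#' is the modal-class share; chance level for four balanced classes is 25%.
#'
#' @param fit A `"strategy_fit"` (fitted or built from printed
#'   coefficients via [printed_fit()]).
#' @param cohort Optional classified cohort to score; defaults to the
#'   fit's own training data.
#' @return A proportion in `[0, 1]`.
#' @export
training_accuracy <- function(fit, cohort = NULL) {
  stopifnot(inherits(fit, "strategy_fit"))
  mf <- if (is.null(cohort)) fit$data else as_model_frame(cohort, fit$binary)
  if (is.null(mf)) {
    po_stop("no cohort to score", "po_invalid_parameter")
  }
  lp <- linear_predictors(fit$coefficients, mf)
  if (fit$binary) {
    pred <- ifelse(lp[, "turner"] > 0, "turner", "non-turner")
  } else {
    all_lp <- cbind(`no-preference` = 0, lp)
    pred <- colnames(all_lp)[max.col(all_lp, ties.method = "first")]
  }
  mean(pred == as.character(mf$classification))
}

#' Wrap printed coefficients as a fit object
#'
#' Builds a `"strategy_fit"` from an externally reported coefficient table
#' (and optionally its standard errors), so the odds-ratio machinery can be
#' applied without refitting. No coefficient covariance is available in
#' this mode, so Wald intervals fall back to the independent-SE
#' approximation.
#'
#' @param coefficients A [coefficient_matrix()].
#' @param standard_errors Optional matching matrix of standard errors.
#' @return A `"strategy_fit"` with `vcov = NULL` and no data.
#' @export
printed_fit <- function(coefficients, standard_errors = NULL) {
  stopifnot(inherits(coefficients, "coef_matrix"))
  if (!is.null(standard_errors)) {
    stopifnot(all(dim(standard_errors) == dim(coefficients)))
    standard_errors <- standard_errors[rownames(coefficients),
                                       colnames(coefficients)]
  }
  new_strategy_fit(coefficients, standard_errors, NULL, NA_real_, NULL, NULL,
                   converged = TRUE, binary = FALSE)
}

#' @export
print.strategy_fit <- function(x, ...) {
  kind <- if (x$binary) "binary logistic (turner vs non-turner)"
          else "multinomial (baseline no-preference)"
  cat(sprintf("<strategy_fit> %s\n", kind))
  if (!is.null(x$data)) {
    cat(sprintf("  n = %d, logLik = %.3f, converged: %s\n", x$n_obs,
                x$log_likelihood, x$converged))
  } else {
    cat("  built from printed coefficients (no data)\n")
  }
  print(round(unclass(x$coefficients), 3))
  invisible(x)
}

#' Serialize a fit summary as JSON
#'
#' Writes coefficients, standard errors, log-likelihood, convergence and
#' (when supplied) likelihood-ratio test rows to a JSON file.
#'
#' @param fit A `"strategy_fit"`.
#' @param path Output path.
#' @param lr_tests Optional result of [likelihood_ratio_tests()].
#' @export
write_fit_json <- function(fit, path, lr_tests = NULL) {
  stopifnot(inherits(fit, "strategy_fit"))
  obj <- list(
    kind = if (fit$binary) "binary" else "multinomial",
    baseline = fit$baseline,
    n_obs = fit$n_obs,
    log_likelihood = fit$log_likelihood,
    converged = fit$converged,
    terms = colnames(fit$coefficients),
    coefficients = apply(fit$coefficients, 1, as.list, simplify = FALSE),
    standard_errors = if (!is.null(fit$standard_errors))
      apply(fit$standard_errors, 1, as.list, simplify = FALSE))
  if (!is.null(lr_tests)) obj$lr_tests <- lr_tests
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
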