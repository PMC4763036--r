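# The multinomial coefficient matrix: dummy-coded linear-predictor
# coefficients for the three non-baseline outcomes, and the softmax
# probability engine built on it.

outcomes_nonbaseline <- function() c("non-turner", "turner", "non-mover")

analysis_classes <- function() {
  c("no-preference", "non-turner", "turner", "non-mover")
}

#' Design terms and factor levels of the classification model
#'
#' The model regresses participant classification on ethnicity, response
#' mode and gender with all interactions, dummy coded against the reference
#' levels Caucasian, pictorial and female. `design_terms()` returns the 12
#' column labels of that design in canonical order; `factor_levels()` the
#' levels of each factor (reference level first).
#'
#' @return `design_terms()`: character vector of 12 term labels.
#'   `factor_levels()`: named list of factor levels.
#' @export
design_terms <- function() {
  c("(Intercept)", "ethnicityChinese", "ethnicityOther", "response_modetext",
    "gendermale", "ethnicityChinese:response_modetext",
    "ethnicityOther:response_modetext", "ethnicityChinese:gendermale",
    "ethnicityOther:gendermale", "response_modetext:gendermale",
    "ethnicityChinese:response_modetext:gendermale",
    "ethnicityOther:response_modetext:gendermale")
}

#' @rdname design_terms
#' @export
factor_levels <- function() {
  list(ethnicity = c("Caucasian", "Chinese", "Other"),
       response_mode = c("pictorial", "text"),
       gender = c("female", "male"))
}

# Dummy-coded design row for one covariate profile, matching design_terms().
design_row <- function(ethnicity, response_mode, gender) {
  lv <- factor_levels()
  if (!(ethnicity %in% lv$ethnicity) || !(response_mode %in% lv$response_mode) ||
      !(gender %in% lv$gender)) {
    po_stop(sprintf("unknown factor level in profile (%s, %s, %s)",
                    ethnicity, response_mode, gender),
            "po_invalid_contrast")
  }
  ch <- as.numeric(ethnicity == "Chinese")
  ot <- as.numeric(ethnicity == "Other")
  tx <- as.numeric(response_mode == "text")
  ml <- as.numeric(gender == "male")
  setNames(c(1, ch, ot, tx, ml, ch * tx, ot * tx, ch * ml, ot * ml, tx * ml,
             ch * tx * ml, ot * tx * ml), design_terms())
}

#' Construct a coefficient matrix
#'
#' Linear-predictor coefficients of the multinomial classification model:
#' one row per non-baseline outcome (non-turner, turner, non-mover; the
#' baseline outcome no-preference has all-zero coefficients and is not
#' stored) and one column per design term (see [design_terms()]).
#'
#' @param x A numeric 3 x 12 matrix. Row and column names, if present, must
#'   match the canonical outcomes and terms (any order); they are reordered.
#' @return An object of class `"coef_matrix"`.
#' @export
coefficient_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || nrow(x) != 3L || ncol(x) != 12L) {
    po_stop("coefficient matrix must be numeric 3 x 12",
            "po_invalid_coefficient")
  }
  if (!is.null(rownames(x))) {
    if (!setequal(rownames(x), outcomes_nonbaseline())) {
      po_stop("coefficient rows must be the three non-baseline outcomes",
              "po_invalid_coefficient")
    }
    x <- x[outcomes_nonbaseline(), , drop = FALSE]
  } else {
    rownames(x) <- outcomes_nonbaseline()
  }
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), design_terms())) {
      po_stop("coefficient columns must match design_terms()",
              "po_invalid_coefficient")
    }
    x <- x[, design_terms(), drop = FALSE]
  } else {
    colnames(x) <- design_terms()
  }
  structure(x, class = c("coef_matrix", class(matrix())))
}

#' Reference coefficient and standard-error tables
#'
#' The multinomial coefficient estimates (and their standard errors)
#' reported by the large classroom study of this task (n = 498 analysed
#' participants), with baseline outcome no-preference and reference levels
#' Caucasian, pictorial, female. These power the worked odds-ratio examples
#' and are the default generating coefficients of the synthetic-cohort
#' module (after capping, see [cap_coefficients()]: the two non-mover
#' estimates near -12 and +10.4 are quasi-separation artifacts).
#'
#' @return A [coefficient_matrix()] (or, for the standard errors, a plain
#'   3 x 12 matrix with the same dimnames).
#' @export
reference_coefficients <- function() {
  coefficient_matrix(matrix(c(
    # non-turner
    1.15, -0.0136, -0.0469, -0.452, -0.766, -0.998, 0.453, 1.35, 1.05,
    0.508, -0.775, -1.08,
    # turner
    0.251, -0.944, -1.06, 0.704, 0.516, 0.156, 0.396, 0.0226, 0.701,
    -0.824, 0.119, -0.276,
    # non-mover
    -0.847, 0.847, 0.847, -0.763, -1.02, -0.249, -12, 0.87, 1.31,
    1.85, -1.37, 10.4
  ), nrow = 3, byrow = TRUE,
  dimnames = list(outcomes_nonbaseline(), design_terms())))
}

#' @rdname reference_coefficients
#' @export
reference_standard_errors <- function() {
  matrix(c(
    0.434, 0.566, 0.58, 0.699, 0.564, 0.915, 1.04, 0.787, 0.821, 0.876,
    1.24, 1.39,
    0.504, 0.744, 0.784, 0.729, 0.605, 0.999, 1.21, 0.988, 1, 0.884,
    1.35, 1.56,
    0.69, 0.822, 0.836, 1.29, 1.03, 1.49, 0.66, 1.25, 1.25, 1.6,
    1.94, 0.66
  ), nrow = 3, byrow = TRUE,
  dimnames = list(outcomes_nonbaseline(), design_terms()))
}

#' Cap extreme coefficients
#'
#' Replaces entries whose magnitude exceeds `bound` by `sign(x) * bound`.
#' Quasi-separation (an outcome never observed in some covariate cell)
#' drives dummy-coded estimates toward plus or minus infinity; capping keeps
#' the implied cell probabilities small but non-degenerate, which matters
#' when the matrix is used to generate synthetic cohorts.
#'
#' @param coefficients A [coefficient_matrix()].
#' @param bound Positive magnitude bound.
#' @return The capped [coefficient_matrix()], with a `"capped"` attribute
#'   listing the replacements (empty data frame when none).
#' @export
cap_coefficients <- function(coefficients, bound = 5) {
  stopifnot(inherits(coefficients, "coef_matrix"))
  check_scalar_number(bound, "bound")
  if (bound <= 0) po_stop("bound must be positive", "po_invalid_parameter")
  idx <- which(abs(coefficients) > bound, arr.ind = TRUE)
  note <- data.frame(outcome = rownames(coefficients)[idx[, 1]],
                     term = colnames(coefficients)[idx[, 2]],
                     original = coefficients[idx],
                     capped = sign(coefficients[idx]) * bound)
  out <- unclass(coefficients)
  out[idx] <- sign(out[idx]) * bound
  out <- coefficient_matrix(out)
  attr(out, "capped") <- note
  out
}

#' Classification probabilities for a covariate profile
#'
#' The softmax link of the multinomial model: with linear predictors
#' `eta_k = x . beta_k` for the non-baseline outcomes and `eta = 0` for the
#' baseline no-preference, the probability of outcome k is
#' `exp(eta_k) / sum_j exp(eta_j)`. Probabilities sum to one and are
#' invariant to adding a constant to every linear predictor.
#'
#' @param ethnicity,response_mode,gender Covariate levels (see
#'   [factor_levels()]).
#' @param coefficients A [coefficient_matrix()].
#' @return A named probability vector over
#'   `c("non-turner", "turner", "non-mover", "no-preference")`.
#' @examples
#' strategy_probabilities("Caucasian", "pictorial", "female")
#' @export
strategy_probabilities <- function(ethnicity, response_mode, gender,
                                   coefficients = reference_coefficients()) {
  stopifnot(inherits(coefficients, "coef_matrix"))
  x <- design_row(ethnicity, response_mode, gender)
  lp <- as.vector(coefficients %*% x)
  if (any(!is.finite(lp))) {
    po_stop("non-finite linear predictor", "po_invalid_coefficient")
  }
  lp <- c(lp, 0)
  names(lp) <- c(rownames(coefficients), "no-preference")
  e <- exp(lp - max(lp))
  e / sum(e)
}
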