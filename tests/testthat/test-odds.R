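ref_profile <- function(...) {
  modifyList(list(ethnicity = "Caucasian", response_mode = "pictorial",
                  gender = "female"), list(...))
}

test_that("odds ratios reproduce the published worked examples", {
  co <- reference_coefficients()
  or <- function(t, b, f, a, bb, ...) {
    prof <- ref_profile(...)
    prof[[f]] <- NULL
    odds_ratio(co, t, b, f, a, bb, profile = prof)$or
  }
  # gender, Caucasian pictorial
  expect_equal(round(or("turner", "non-turner", "gender", "male", "female"),
                     1), 3.6)
  # Chinese contrasts at male pictorial
  expect_equal(round(or("non-turner", "no-preference", "ethnicity",
                        "Chinese", "Caucasian", gender = "male"), 2), 3.81)
  expect_equal(round(or("turner", "non-mover", "ethnicity", "Caucasian",
                        "Chinese", gender = "male"), 2), 13.99)
  expect_equal(round(or("turner", "non-mover", "ethnicity", "Caucasian",
                        "Chinese"), 0), 6)
  # response mode
  expect_equal(round(or("non-turner", "turner", "response_mode", "pictorial",
                        "text"), 2), 3.18)
  expect_equal(round(or("non-turner", "turner", "response_mode", "pictorial",
                        "text", ethnicity = "Chinese", gender = "male"), 1),
               6.5)
  expect_equal(round(or("non-turner", "turner", "response_mode", "pictorial",
                        "text", ethnicity = "Chinese"), 2), 10.07)
  expect_equal(round(or("non-turner", "no-preference", "response_mode",
                        "pictorial", "text", ethnicity = "Chinese",
                        gender = "male"), 2), 5.57)
  expect_equal(round(or("non-turner", "no-preference", "response_mode",
                        "pictorial", "text", ethnicity = "Chinese"), 2), 4.26)
  # rounding of the printed coefficients: recomputed within 1%
  expect_equal(or("turner", "non-turner", "ethnicity", "Caucasian", "Chinese",
                  gender = "male"), 9.58, tolerance = 0.01)
  expect_equal(or("non-turner", "turner", "ethnicity", "Other", "Caucasian",
                  gender = "male"), 3.93, tolerance = 0.01)
})

test_that("odds ratios equal softmax probability-odds ratios (exp-linearity)", {
  co <- cap_coefficients(reference_coefficients())
  lv <- factor_levels()
  set.seed(5)
  for (i in 1:25) {
    f <- sample(names(lv), 1)
    ab <- sample(lv[[f]], 2)
    prof <- lapply(lv[setdiff(names(lv), f)], sample, size = 1)
    pair <- sample(c("no-preference", "non-turner", "turner", "non-mover"), 2)
    rec <- odds_ratio(co, pair[1], pair[2], f, ab[1], ab[2], profile = prof)
    pa <- prof; pa[[f]] <- ab[1]
    pb <- prof; pb[[f]] <- ab[2]
    p_a <- strategy_probabilities(pa$ethnicity, pa$response_mode, pa$gender, co)
    p_b <- strategy_probabilities(pb$ethnicity, pb$response_mode, pb$gender, co)
    oracle <- (p_a[pair[1]] / p_a[pair[2]]) / (p_b[pair[1]] / p_b[pair[2]])
    expect_equal(rec$or, unname(oracle), tolerance = 1e-10)
    # reciprocal symmetry
    mirror <- odds_ratio(co, pair[2], pair[1], f, ab[1], ab[2],
                         profile = prof)
    expect_equal(rec$or * mirror$or, 1, tolerance = 1e-10)
    # identical levels give OR 1
    same <- odds_ratio(co, pair[1], pair[2], f, ab[1], ab[1], profile = prof)
    expect_equal(same$or, 1, tolerance = 1e-12)
  }
})

test_that("baseline rotations enumerate every reference combination", {
  rot <- enumerate_rotations()
  expect_identical(nrow(rot), 12L)
  expect_identical(nrow(unique(rot)), 12L)
  expect_identical(nrow(enumerate_rotations(list(a = c("x", "y")))), 2L)
})

test_that("odds ratios are invariant to the baseline rotation of the fit", {
  cells <- reference_cell_sizes()
  cfg <- generator_config(cell_sizes = cells, seed = 21)
  coh <- preprocess_cohort(generate_cohort(cfg))$cohort
  fit <- fit_strategy_model(coh)
  rec <- odds_ratio(fit, "turner", "non-turner", "gender", "male", "female",
                    profile = list(ethnicity = "Chinese",
                                   response_mode = "text"))
  # refit under a rotated parametrization (different reference levels) and
  # recompute the same contrast from predicted probabilities
  mf <- fit$data
  mf$ethnicity <- relevel(factor(as.character(mf$ethnicity)), "Chinese")
  mf$response_mode <- relevel(factor(as.character(mf$response_mode)), "text")
  mf$gender <- relevel(factor(as.character(mf$gender)), "male")
  m2 <- nnet::multinom(classification ~ ethnicity * response_mode * gender,
                       data = mf, trace = FALSE, maxit = 300, reltol = 1e-12)
  nd <- data.frame(ethnicity = factor("Chinese", levels(mf$ethnicity)),
                   response_mode = factor("text", levels(mf$response_mode)),
                   gender = factor(c("male", "female"), levels(mf$gender)))
  pp <- predict(m2, nd, type = "probs")
  rotated <- (pp[1, "turner"] / pp[1, "non-turner"]) /
    (pp[2, "turner"] / pp[2, "non-turner"])
  expect_equal(rec$or, unname(rotated), tolerance = 1e-3)
})

test_that("significance filtering applies the reporting rules", {
  cells <- reference_cell_sizes()
  cells$n <- cells$n * 4L
  coh <- preprocess_cohort(generate_cohort(
    generator_config(cell_sizes = cells, seed = 33)))$cohort
  fit <- fit_strategy_model(coh)
  ors <- significant_ors(fit)
  if (nrow(ors) > 0) {
    expect_true(all(ors$or > 1))
    expect_true(all(ors$or >= 0.001 & ors$or <= 100))
    expect_true(all(ors$ci_low > 1 | ors$ci_high < 1))
    expect_false(any(ors$approx))
    # mirror dedup: the reciprocal (swapped-outcome, same-levels) record of
    # a reported OR is below one and must be absent
    for (i in seq_len(min(nrow(ors), 5))) {
      dup <- ors$target == ors$baseline[i] & ors$baseline == ors$target[i] &
        ors$factor == ors$factor[i] & ors$level_a == ors$level_a[i] &
        ors$level_b == ors$level_b[i]
      prof_match <- TRUE
      for (col in c("ethnicity", "response_mode", "gender")) {
        prof_match <- prof_match &
          (is.na(ors[[col]][i]) == is.na(ors[[col]]) &
             (is.na(ors[[col]][i]) | ors[[col]] == ors[[col]][i]))
      }
      expect_false(any(dup & prof_match))
    }
  }
  # a zero point estimate can never be significant
  zero <- printed_fit(coefficient_matrix(matrix(0, 3, 12)),
                      reference_standard_errors())
  rec <- odds_ratio(zero, "turner", "non-turner", "gender", "male", "female",
                    profile = list(ethnicity = "Caucasian",
                                   response_mode = "pictorial"))
  expect_false(rec$significant)
  expect_true(rec$approx)
})

test_that("printed-coefficient mode flags extreme sparse-cell odds ratios", {
  pf <- printed_fit(reference_coefficients(), reference_standard_errors())
  # the quasi-separated non-mover estimate implies an OR far outside the
  # reporting window
  rec <- odds_ratio(pf, "non-mover", "no-preference", "response_mode",
                    "text", "pictorial",
                    profile = list(ethnicity = "Other", gender = "female"))
  expect_true(rec$or < 0.001 || rec$or > 100)
  ors <- suppressWarnings(significant_ors(pf))
  expect_true(all(ors$or >= 0.001 & ors$or <= 100))
  expect_true(all(ors$approx))
})

test_that("invalid contrasts are refused", {
  co <- reference_coefficients()
  expect_error(odds_ratio(co, "turner", "non-turner", "gender", "male",
                          "unknown", profile = ref_profile()),
               class = "po_invalid_contrast")
  expect_error(odds_ratio(co, "turner", "non-turner", "handedness", "l", "r",
                          profile = ref_profile()),
               class = "po_invalid_contrast")
  expect_error(odds_ratio(co, "turner", "non-turner", "gender", "male",
                          "female", profile = list(ethnicity = "Caucasian")),
               class = "po_invalid_contrast")
})
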