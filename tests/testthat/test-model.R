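# Well-conditioned test cohort: mildly-capped coefficients and scaled-up
# cells keep every class populated in every covariate cell, so fits are
# away from the quasi-separation regime the raw reference values induce.
fit_test_cohort <- function(seed = 7, n_scale = 10) {
  cells <- reference_cell_sizes()
  cells$n <- cells$n * n_scale
  cfg <- generator_config(cell_sizes = cells,
                          coefficients = cap_coefficients(
                            reference_coefficients(), 1),
                          seed = seed)
  preprocess_cohort(generate_cohort(cfg))$cohort
}

test_that("the multinomial fit converges and matches its own softmax", {
  coh <- fit_test_cohort()
  fit <- fit_strategy_model(coh)
  expect_true(fit$converged)
  expect_s3_class(fit$coefficients, "coef_matrix")
  expect_true(all(fit$standard_errors > 0))
  expect_true(is.finite(fit$log_likelihood))
  # fitted probabilities from the package's own softmax engine agree with
  # nnet's predictions
  p_nnet <- predict(fit$model, type = "probs")
  lv <- factor_levels()
  for (i in c(1, 50, 200)) {
    p_own <- strategy_probabilities(as.character(fit$data$ethnicity[i]),
                                    as.character(fit$data$response_mode[i]),
                                    as.character(fit$data$gender[i]),
                                    fit$coefficients)
    expect_equal(unname(p_own[colnames(p_nnet)[-1]]),
                 unname(p_nnet[i, -1]), tolerance = 1e-6)
  }
})

test_that("row order does not change the fit", {
  coh <- fit_test_cohort()
  set.seed(1)
  shuffled <- coh[sample(nrow(coh)), ]
  f1 <- fit_strategy_model(coh)
  f2 <- fit_strategy_model(shuffled)
  expect_equal(unclass(f1$coefficients), unclass(f2$coefficients),
               tolerance = 1e-5)
})

test_that("duplicating every row preserves estimates and doubles LR statistics", {
  coh <- fit_test_cohort()
  f1 <- fit_strategy_model(coh)
  f2 <- fit_strategy_model(rbind(coh, coh))
  expect_equal(unclass(f1$coefficients), unclass(f2$coefficients),
               tolerance = 1e-3)
  lr1 <- likelihood_ratio_tests(f1, terms = "response_mode")
  lr2 <- likelihood_ratio_tests(f2, terms = "response_mode")
  expect_equal(lr2$lr_chi2, 2 * lr1$lr_chi2, tolerance = 0.02)
})

test_that("term tests carry the design's degrees of freedom", {
  coh <- fit_test_cohort()
  fit <- fit_strategy_model(coh)
  lr <- likelihood_ratio_tests(fit)
  expect_identical(lr$term,
                   c("ethnicity", "response_mode", "gender",
                     "ethnicity:response_mode", "ethnicity:gender",
                     "response_mode:gender",
                     "ethnicity:response_mode:gender"))
  expect_identical(lr$df, c(6L, 3L, 3L, 6L, 6L, 3L, 6L))
  expect_true(all(lr$lr_chi2 >= 0))
  expect_true(all(lr$p >= 0 & lr$p <= 1))
  bfit <- fit_binary_logistic(coh)
  lrb <- likelihood_ratio_tests(bfit)
  expect_identical(lrb$df, c(2L, 1L, 1L, 2L, 2L, 1L, 2L))
})

test_that("type II LR tests agree with car::Anova", {
  skip_if_not_installed("car")
  coh <- fit_test_cohort()
  fit <- fit_strategy_model(coh)
  mine <- likelihood_ratio_tests(fit, type = "II")
  m <- nnet::multinom(classification ~ ethnicity * response_mode * gender,
                      data = fit$data, trace = FALSE, maxit = 200,
                      reltol = 1e-10)
  ref <- car::Anova(m, type = "II")
  expect_equal(mine$lr_chi2, ref[["LR Chisq"]], tolerance = 1e-3)
  expect_equal(mine$df, as.integer(ref[["Df"]]))
})

test_that("intercept-only predictions hit the modal-class share", {
  coh <- fit_test_cohort()
  freq <- table(factor(coh$classification,
                       c("no-preference", "non-turner", "turner",
                         "non-mover"))) / nrow(coh)
  intercepts <- log(as.numeric(freq[-1]) / as.numeric(freq[1]))
  co <- matrix(0, 3, 12)
  co[, 1] <- intercepts
  f0 <- printed_fit(coefficient_matrix(co))
  acc0 <- training_accuracy(f0, coh)
  expect_equal(acc0, max(freq), tolerance = 1e-12)
  # full fit can only refine the intercept-only predictor
  fit <- fit_strategy_model(coh)
  expect_gte(training_accuracy(fit), acc0)
})

test_that("a perfectly separated cohort is fitted with accuracy one", {
  # one deterministic class per ethnicity x response-mode cell, covering
  # all four analysis classes (no-preference cells answer in a 2-2 split)
  cells <- expand.grid(ethnicity = c("Caucasian", "Chinese", "Other"),
                       response_mode = c("pictorial", "text"),
                       gender = c("female", "male"),
                       stringsAsFactors = FALSE)
  cells$n <- 30
  strat_of <- list(
    Caucasian.pictorial = "turner", Chinese.pictorial = "non-turner",
    Other.pictorial = "non-mover", Caucasian.text = "no-preference",
    Chinese.text = "turner", Other.text = "non-mover")
  np_answers <- c(strategy_answers("turner")[1:2],
                  strategy_answers("non-turner")[3:4])
  coh <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    s <- strat_of[[paste(cells$ethnicity[i], cells$response_mode[i],
                         sep = ".")]]
    do.call(rbind, lapply(seq_len(cells$n[i]), function(k) {
      make_row(sprintf("Q%d_%d", i, k), gender = cells$gender[i],
               ethnicity = cells$ethnicity[i],
               response_mode = cells$response_mode[i],
               strategy = if (s == "no-preference") NULL else s,
               answers = if (s == "no-preference") np_answers else NULL)
    }))
  }))
  coh <- classify_cohort(coh)
  expect_setequal(unique(coh$classification),
                  c("turner", "non-turner", "non-mover", "no-preference"))
  fit <- suppressWarnings(fit_strategy_model(coh))
  expect_equal(training_accuracy(fit), 1)
})

test_that("binary logistic needs both classes and matches the two-class design", {
  coh <- fit_test_cohort()
  bfit <- fit_binary_logistic(coh)
  expect_true(bfit$converged)
  expect_identical(rownames(bfit$coefficients), "turner")
  only_t <- classify_cohort(make_cohort(rep("turner", 10)))
  expect_error(fit_binary_logistic(only_t), class = "po_rank_deficiency")
})

test_that("empty design cells are reported by name", {
  coh <- fit_test_cohort()
  coh <- coh[!(coh$ethnicity_pooled == "Other" &
                 coh$response_mode == "text"), ]
  expect_error(fit_strategy_model(coh), class = "po_rank_deficiency")
  expect_error(fit_strategy_model(coh), "Other")
})

test_that("spinners must be excluded before fitting", {
  coh <- classify_cohort(make_cohort(c(rep("turner", 5), "spinner")))
  expect_error(fit_strategy_model(coh), class = "po_invalid_parameter")
})
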