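test_that("softmax probabilities behave like a baseline-category model", {
  zero <- coefficient_matrix(matrix(0, 3, 12))
  expect_equal(unname(strategy_probabilities("Caucasian", "pictorial",
                                             "female", zero)),
               rep(0.25, 4))
  # reference profile under the reported intercepts
  p <- strategy_probabilities("Caucasian", "pictorial", "female")
  expect_equal(unname(round(p, 3)),
               c(0.538, 0.219, 0.073, 0.170))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  bad <- unclass(reference_coefficients())
  bad[1, 1] <- Inf
  expect_error(strategy_probabilities("Caucasian", "pictorial", "female",
                                      coefficient_matrix(bad)),
               class = "po_invalid_coefficient")
})

test_that("probabilities equal the softmax computed by hand for any profile", {
  co <- reference_coefficients()
  lv <- factor_levels()
  for (e in lv$ethnicity) for (m in lv$response_mode) for (g in lv$gender) {
    p <- strategy_probabilities(e, m, g, co)
    # independent hand computation from the dummy-coding definition
    x <- c(1, e == "Chinese", e == "Other", m == "text", g == "male",
           (e == "Chinese") * (m == "text"), (e == "Other") * (m == "text"),
           (e == "Chinese") * (g == "male"), (e == "Other") * (g == "male"),
           (m == "text") * (g == "male"),
           (e == "Chinese") * (m == "text") * (g == "male"),
           (e == "Other") * (m == "text") * (g == "male"))
    lp <- c(drop(unclass(co) %*% x), 0)
    expect_equal(unname(p), unname(exp(lp) / sum(exp(lp))), tolerance = 1e-12)
  }
})

test_that("capping replaces only out-of-bound entries and records them", {
  capped <- cap_coefficients(reference_coefficients(), 5)
  note <- attr(capped, "capped")
  expect_identical(nrow(note), 2L)
  expect_setequal(note$original, c(-12, 10.4))
  expect_identical(
    capped["non-mover", "ethnicityOther:response_modetext"], -5)
  expect_identical(
    capped["non-mover", "ethnicityOther:response_modetext:gendermale"], 5)
  # untouched entries identical
  keep <- unclass(reference_coefficients())
  keep[abs(keep) > 5] <- sign(keep[abs(keep) > 5]) * 5
  expect_equal(unclass(capped), keep, ignore_attr = TRUE)
  # identity on an already-bounded matrix
  again <- cap_coefficients(capped, 5)
  expect_equal(unclass(again), unclass(capped), ignore_attr = TRUE)
  expect_identical(nrow(attr(again, "capped")), 0L)
  # capped matrix still yields valid probabilities everywhere
  lv <- factor_levels()
  for (e in lv$ethnicity) for (m in lv$response_mode) for (g in lv$gender) {
    p <- strategy_probabilities(e, m, g, capped)
    expect_true(all(p > 0) && abs(sum(p) - 1) < 1e-12)
  }
})

test_that("reference cell sizes reproduce the cohort margins", {
  cs <- reference_cell_sizes()
  expect_identical(sum(cs$n), 501L)
  expect_identical(sum(cs$n[cs$response_mode == "pictorial"]), 313L)
  expect_identical(sum(cs$n[cs$ethnicity == "Caucasian" &
                              cs$gender == "male"]), 117L)
  cohort <- generate_cohort(generator_config(seed = 1))
  expect_identical(nrow(cohort), 501L)
  got <- as.data.frame(table(cohort$ethnicity_pooled, cohort$response_mode,
                             cohort$gender))
  expect_identical(sum(got$Freq), 501L)
})

test_that("generation is deterministic and lapse-free generation round-trips", {
  c1 <- generate_cohort(generator_config(seed = 5))
  c2 <- generate_cohort(generator_config(seed = 5))
  expect_identical(c1, c2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(c1, f1); write_cohort_csv(c2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  c0 <- generate_cohort(generator_config(lapse_rate = 0, seed = 8))
  cls <- classify_cohort(c0)$classification
  expect_identical(cls, attr(c0, "latent_class"))
})

test_that("no-preference participants always emit a 2-2 split of two strategies", {
  coh <- generate_cohort(generator_config(seed = 12))
  latent <- attr(coh, "latent_class")
  labs <- label_cohort(coh)
  npr <- latent == "no-preference"
  counts <- t(apply(labs[npr, , drop = FALSE], 1, function(r) {
    sort(as.vector(table(r)), decreasing = TRUE)[1:2]
  }))
  expect_true(all(counts[, 1] == 2 & counts[, 2] == 2))
})

test_that("lapse-driven misclassification matches the exact enumeration oracle", {
  eps <- 0.05
  p_exact <- exact_misclassification("turner", eps)
  # large single-cell Monte Carlo draw through the generator itself
  cells <- data.frame(ethnicity = "Caucasian", response_mode = "pictorial",
                      gender = "male", n = 20000)
  # all-turner latent population: put full mass on turner
  co <- matrix(0, 3, 12); co[, 1] <- c(-30, 30, -30)
  cfg <- generator_config(cell_sizes = cells,
                          coefficients = coefficient_matrix(co),
                          lapse_rate = eps, seed = 31)
  coh <- generate_cohort(cfg)
  expect_true(all(attr(coh, "latent_class") == "turner"))
  cls <- classify_cohort(coh)$classification
  mis <- mean(cls != "turner")
  se <- sqrt(p_exact * (1 - p_exact) / nrow(coh))
  expect_lt(abs(mis - p_exact), 4 * se)
  # the bound stated by the lapse model: at most P(>= 2 lapses)
  p_two_lapse <- 1 - (1 - eps)^4 - 4 * eps * (1 - eps)^3
  expect_lte(p_exact, p_two_lapse)
})

test_that("classification frequencies converge to the softmax mixture", {
  cells <- reference_cell_sizes()
  cells$n <- round(cells$n / sum(cells$n) * 10000)
  capped <- cap_coefficients(reference_coefficients())
  cfg <- generator_config(cell_sizes = cells, coefficients = capped,
                          lapse_rate = 0, seed = 77)
  coh <- generate_cohort(cfg)
  cls <- classify_cohort(coh)$classification
  n <- nrow(coh)
  expected <- rowSums(vapply(seq_len(nrow(cells)), function(i) {
    cells$n[i] / n * strategy_probabilities(cells$ethnicity[i],
                                            cells$response_mode[i],
                                            cells$gender[i], capped)
  }, numeric(4)))
  for (k in names(expected)) {
    p <- expected[k]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(cls == k) - p), 3 * se)
  }
})

test_that("degenerate generator configurations are refused", {
  cells <- reference_cell_sizes()
  cells$n <- 0
  expect_error(generate_cohort(generator_config(cell_sizes = cells)),
               class = "po_empty_cohort")
  expect_error(generator_config(lapse_rate = 1.2),
               class = "po_invalid_parameter")
})
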