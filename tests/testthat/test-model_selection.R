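test_that("stratified split reproduces the 44/23 and 24/13 design", {
  status <- c(rep("control", 67), rep("case", 37))
  sp <- split_cohort(status, seed = 1)
  expect_equal(sum(status[sp$train] == "control"), 44)
  expect_equal(sum(status[sp$train] == "case"), 24)
  expect_equal(sum(status[sp$test] == "control"), 23)
  expect_equal(sum(status[sp$test] == "case"), 13)
  expect_setequal(c(sp$train, sp$test), seq_along(status))   # exact partition
  # deterministic given seed; different seeds give different partitions
  expect_identical(sp, split_cohort(status, seed = 1))
  others <- vapply(2:11, function(s)
    identical(split_cohort(status, seed = s)$train, sp$train), logical(1))
  expect_false(all(others))
  expect_error(split_cohort(c("case", "control")), "too small")
})

test_that("cross-validation folds partition the training data, stratified", {
  y <- c(rep(0L, 44), rep(1L, 24))
  folds <- methpanel:::make_folds(y, 4, seed = 3)
  expect_equal(sort(unique(folds)), 1:4)
  expect_length(folds, 68)
  for (f in 1:4) {
    expect_gte(sum(folds == f & y == 1), 2)
    expect_gte(sum(folds == f & y == 0), 2)
  }
})

test_that("a perfectly separating marker ranks first with cv AUC near 1", {
  set.seed(61)
  n <- 40
  y <- rep(0:1, each = n / 2)
  x <- cbind(perfect = y,
             noise1 = rbinom(n, 1, 0.5),
             noise2 = rbinom(n, 1, 0.5),
             noise3 = rbinom(n, 1, 0.5))
  rk <- best_subsets(x, y, max_size = 1, seed = 5)
  expect_equal(rk$covariates[1], "perfect")
  expect_gt(rk$cv_auc[1], 0.99)
})

test_that("ranking is exhaustive, deterministic, and reports sane AUCs", {
  cohort <- small_cohort(seed = 67, n_controls = 24, n_cases = 14)
  pm <- build_panel_matrix(cohort$cq)
  ctrl <- representative_cores(pm, cohort$samples, "control_best")
  cancer <- representative_cores(pm, cohort$samples, "case_cancer")
  units <- rbind(ctrl, cancer)
  y <- as.integer(units$patient_id %in% cancer$patient_id)
  x <- model_covariates(pm, units$core_id, "indicator")
  rk <- best_subsets(x, y, max_size = 2, seed = 9)
  expect_equal(nrow(rk), 24 + choose(24, 2))
  expect_true(all(rk$cv_auc >= 0 & rk$cv_auc <= 1))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$cv_auc) <= 1e-12))   # sorted descending
  rk2 <- best_subsets(x, y, max_size = 2, seed = 9)
  expect_identical(rk$covariates, rk2$covariates)
  expect_identical(rk$cv_auc, rk2$cv_auc)
  top <- top_models(rk, n_per_size = 5)
  expect_equal(as.integer(table(top$size)), c(5L, 5L))
  # age-augmented enumeration doubles the candidate list
  x_age <- cbind(x, age = rnorm(nrow(x), 65, 8))
  rk_age <- best_subsets(x_age, y, max_size = 1, include_age = TRUE, seed = 9)
  expect_equal(nrow(rk_age), 48)
  expect_true(any(grepl("\\+ age$", rk_age$covariates)))
})

test_that("level-mode covariates use semi-quantitative levels", {
  pm <- pm_from_rows(rbind(c(2.5, 0), c(0, 1), c(NA, 3)))
  xi <- model_covariates(pm, rownames(pm$call), "indicator")
  xl <- model_covariates(pm, rownames(pm$call), "level")
  expect_equal(unname(xi[, 1]), c(1, 0, 0))   # missing treated as not detected
  expect_equal(unname(xl[, 1]), c(2.5, 0, 0))
  expect_equal(unname(xl[, 2]), c(0, 1, 3))
})

test_that("frozen-coefficient evaluation never touches training quantities", {
  cohort <- small_cohort(seed = 71, n_controls = 24, n_cases = 14)
  pm <- build_panel_matrix(cohort$cq)
  ctrl <- representative_cores(pm, cohort$samples, "control_best")
  cancer <- representative_cores(pm, cohort$samples, "case_cancer")
  units <- rbind(ctrl, cancer)
  y <- as.integer(units$patient_id %in% cancer$patient_id)
  x <- model_covariates(pm, units$core_id, "indicator")
  sp <- split_cohort(ifelse(y == 1, "case", "control"), seed = 2)
  rk <- best_subsets(x[sp$train, ], y[sp$train], max_size = 1, seed = 2)
  auc1 <- evaluate_frozen(rk$coefficients[[1]], x[sp$test, ], y[sp$test])
  # shuffling test labels changes test AUC but not the training-side ranking
  y_shuf <- withr::with_seed(5, sample(y[sp$test]))
  auc2 <- evaluate_frozen(rk$coefficients[[1]], x[sp$test, ], y_shuf)
  rk_again <- best_subsets(x[sp$train, ], y[sp$train], max_size = 1, seed = 2)
  expect_identical(rk$cv_auc, rk_again$cv_auc)
  expect_identical(rk$coefficients, rk_again$coefficients)
  expect_false(isTRUE(all.equal(auc1, auc2)))
  # zero coefficients tie all scores: AUC exactly one half
  zero <- setNames(rep(0, 2), c("(Intercept)", colnames(x)[1]))
  expect_equal(evaluate_frozen(zero, x[sp$test, ], y[sp$test]), 0.5)
  # monotone risk equal to the outcome ordering gives AUC 1
  xm <- matrix(c(0, 1, 2, 3, 4, 5), ncol = 1,
               dimnames = list(NULL, "ADCY4"))
  one <- setNames(c(0, 1), c("(Intercept)", "ADCY4"))
  expect_equal(evaluate_frozen(one, xm, c(0, 0, 0, 1, 1, 1)), 1)
  miss <- setNames(c(0, 1), c("(Intercept)", "NOT_A_MARKER"))
  expect_error(evaluate_frozen(miss, x[sp$test, ], y[sp$test]), "absent")
})

test_that("ridge-stabilised fits stay finite under complete separation", {
  y <- rep(0:1, each = 10)
  x <- matrix(y, ncol = 1, dimnames = list(NULL, "m"))
  fit <- methpanel:::ridge_logistic(x, y)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(fit$converged)
  sc <- methpanel:::logistic_scores(fit$coefficients, x)
  expect_true(all(sc[y == 1] > sc[y == 0]))
})

test_that("strong-marker models achieve high out-of-sample AUC on default cohorts", {
  aucs <- vapply(1:5, function(s) {
    cohort <- generate_cohort(cohort_config(seed = 100 + s))
    pm <- build_panel_matrix(cohort$cq)
    ctrl <- representative_cores(pm, cohort$samples, "control_best")
    cancer <- representative_cores(pm, cohort$samples, "case_cancer")
    units <- rbind(ctrl, cancer)
    y <- as.integer(units$patient_id %in% cancer$patient_id)
    x <- model_covariates(pm, units$core_id, "indicator")
    sp <- split_cohort(ifelse(y == 1, "case", "control"), seed = s)
    fit <- methpanel:::ridge_logistic(x[sp$train, c("ADCY4", "KIFC2")],
                                      y[sp$train])
    evaluate_frozen(fit$coefficients, x[sp$test, ], y[sp$test])
  }, numeric(1))
  expect_gt(mean(aucs), 0.9)
})
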