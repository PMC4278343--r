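test_that("Wald intervals match hand-checked values and stay unclipped", {
  expect_equal(round_half_up(wald_ci(33, 37)), cbind(lower = 0.79, upper = 0.99))
  ci <- wald_ci(36, 37)
  expect_gt(ci[, "upper"], 1)                       # no clipping
  expect_equal(round_half_up(ci), cbind(lower = 0.92, upper = 1.03))
  expect_true(all(is.na(wald_ci(37, 37))))          # degenerate p = 1
  expect_true(all(is.na(wald_ci(0, 67))))           # degenerate p = 0
  expect_error(wald_ci(1, 0), "n must be")
  # continuity correction widens each side by exactly 1/(2n)
  plain <- wald_ci(30, 40)
  corr <- wald_ci(30, 40, continuity = TRUE)
  expect_equal(corr[, "lower"], plain[, "lower"] - 1 / 80)
  expect_equal(corr[, "upper"], plain[, "upper"] + 1 / 80)
})

test_that("interval rendering uses half-up rounding and -- for degenerate rows", {
  expect_equal(format_ci(0.785, 0.995), "(0.79, 1.00)")   # half-up, not banker's
  expect_equal(format_ci(NA, NA), "--")
  expect_equal(round_half_up(c(0.005, 0.015, -0.005)), c(0.01, 0.02, -0.01))
})

test_that("per-marker operating characteristics use per-cell denominators", {
  # case group: marker m2 missing on one core, m3 missing everywhere
  case_lv <- rbind(c(2, 1, NA), c(3, NA, NA), c(0, 4, NA))
  ctrl_lv <- rbind(c(0, 0, 1), c(0, 2, 0))
  pm <- pm_from_rows(rbind(case_lv, ctrl_lv))
  cases <- paste0("c", 1:3); ctrls <- paste0("c", 4:5)
  expect_error(marker_operating_characteristics(pm, cases, ctrls),
               "all cells missing.*m3")
  pm2 <- pm_from_rows(rbind(case_lv[, 1:2], ctrl_lv[, 1:2]))
  oc <- marker_operating_characteristics(pm2, cases, ctrls)
  expect_equal(oc$tp, c(2L, 2L))
  expect_equal(oc$n_case, c(3L, 2L))      # m2 denominator reduced by missing
  expect_equal(oc$sensitivity, c(2 / 3, 1))
  expect_equal(oc$tn, c(2L, 1L))
  expect_true(is.na(oc$sens_upper[2]))    # p = 1 -> undefined CI
  expect_error(marker_operating_characteristics(pm2, character(0), ctrls),
               "non-empty")
})

test_that("perfectly separated synthetic classes give sens = spec = 1", {
  profiles <- default_profiles(dropout_rate = 0)
  profiles$cancer <- tissue_profile("cancer",
                                    setNames(rep(1, 24), panel_markers()),
                                    dropout_rate = 0)
  p0 <- setNames(rep(0, 24), panel_markers())
  profiles$control_benign <- tissue_profile("control_benign", p0, dropout_rate = 0)
  profiles$control_abnormal <- tissue_profile("control_abnormal", p0, dropout_rate = 0)
  cohort <- generate_cohort(cohort_config(n_controls = 8, n_cases = 6,
                                          profiles = profiles, seed = 4))
  pm <- build_panel_matrix(cohort$cq)
  ctrl <- representative_cores(pm, cohort$samples, "control_best")
  cancer <- representative_cores(pm, cohort$samples, "case_cancer")
  oc <- marker_operating_characteristics(pm, cancer$core_id, ctrl$core_id)
  expect_true(all(oc$sensitivity == 1))
  expect_true(all(oc$specificity == 1))
})

test_that("k-of-N rule counts match hand enumeration", {
  res <- k_of_n_rule(case_counts = c(9, 5, 3), control_counts = c(1, 0, 6), k = 5)
  expect_equal(res$tp, 2); expect_equal(res$fn, 1)
  expect_equal(res$tn, 2); expect_equal(res$fp, 1)
  expect_equal(res$sensitivity, 2 / 3)
  expect_equal(res$specificity, 2 / 3)
  expect_equal(res$ppv, 2 / 3)
  expect_equal(res$npv, 2 / 3)
  # k = 1 with all case counts >= 1 is fully sensitive
  expect_equal(k_of_n_rule(c(2, 1, 7), c(0, 1), 1)$sensitivity, 1)
  # PPV consistency on integers: ppv * (tp + fp) = tp exactly
  expect_equal(res$ppv * (res$tp + res$fp), res$tp)
})

test_that("rule sweep is monotone: sens non-increasing, spec non-decreasing in k", {
  set.seed(8)
  for (rep in 1:5) {
    case_counts <- sample(0:24, 30, replace = TRUE)
    ctrl_counts <- sample(0:24, 40, replace = TRUE)
    sweep <- rule_sweep(case_counts, ctrl_counts)
    expect_true(all(diff(sweep$sensitivity) <= 0))
    expect_true(all(diff(sweep$specificity) >= 0))
  }
})

test_that("ROC AUC equals the Mann-Whitney statistic with ties one half", {
  expect_equal(roc_curve(c(2, 3), c(0, 1))$auc, 1)           # perfect separation
  expect_equal(roc_curve(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)   # identical groups
  expect_equal(roc_curve(c(3, 1), c(1, 0))$auc, 0.875)       # (3 wins + .5)/4
  expect_error(roc_curve(numeric(0), c(1)), "non-empty")
})

test_that("ROC AUC agrees with brute-force pairwise comparison", {
  set.seed(17)
  for (rep in 1:20) {
    n1 <- sample(2:100, 1); n0 <- sample(2:100, 1)
    cs <- sample(0:24, n1, replace = TRUE) + rbinom(n1, 1, 0.5) * 0.5
    ks <- sample(0:24, n0, replace = TRUE)
    r <- roc_curve(cs, ks)
    expect_equal(r$auc, brute_force_auc(cs, ks))
  }
})

test_that("ROC curve points are monotone and the trapezoid equals the AUC", {
  set.seed(19)
  cs <- rpois(40, 10); ks <- rpois(50, 4)
  r <- roc_curve(cs, ks)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(utils::tail(r$points$fpr, 1), 1)
  expect_equal(utils::tail(r$points$tpr, 1), 1)
  trapz <- sum(diff(r$points$fpr) *
                 (utils::head(r$points$tpr, -1) + utils::tail(r$points$tpr, -1)) / 2)
  expect_equal(trapz, r$auc)
})

test_that("count-then-level scoring only breaks ties within equal counts", {
  pm <- pm_from_rows(rbind(c(5, 0, 0), c(1, 1, 0), c(0.2, 0.3, 0.1)))
  sc <- panel_scores(pm, definition = "count_then_level")
  counts <- count_positive_markers(pm)
  expect_equal(floor(unname(sc)), as.numeric(counts))   # level term < 1
  expect_lt(sc["c1"], sc["c2"])                         # count dominates level
  expect_gt(sc["c3"], sc["c2"] - 2)                     # sanity on ordering scale
})

test_that("sequential marker combinations reduce to their boundary cases", {
  cohort <- small_cohort(seed = 31)
  pm <- build_panel_matrix(cohort$cq)
  ctrl <- representative_cores(pm, cohort$samples, "control_best")
  cancer <- representative_cores(pm, cohort$samples, "case_cancer")
  seq_markers <- c("HOXB5", "RASSF5", "ADCY4", "SOCS3", "RASSF1")
  curves <- marker_combination_roc(pm, seq_markers, cancer$core_id, ctrl$core_id)
  expect_length(curves, 5)
  # prefix of length 1 equals the single-marker ROC
  single <- roc_curve(
    panel_scores(pm_subset(pm, markers = "HOXB5"), cancer$core_id, "count_then_level"),
    panel_scores(pm_subset(pm, markers = "HOXB5"), ctrl$core_id, "count_then_level"))
  expect_equal(curves[[1]]$auc, single$auc)
  # prefix of all 24 markers reproduces the full-panel ROC
  full <- marker_combination_roc(pm, panel_markers(), cancer$core_id, ctrl$core_id)
  whole <- roc_curve(panel_scores(pm, cancer$core_id, "count_then_level"),
                     panel_scores(pm, ctrl$core_id, "count_then_level"))
  expect_equal(full[[24]]$auc, whole$auc)
  expect_error(marker_combination_roc(pm, "NOPE", cancer$core_id, ctrl$core_id),
               "unknown marker")
})

test_that("AUC cross-checks against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  cs <- rnorm(60, 1); ks <- rnorm(80)
  r <- roc_curve(cs, ks)
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, 60), rep(0, 80)), predictor = c(cs, ks),
    quiet = TRUE, direction = "<"))
  expect_equal(r$auc, as.numeric(ref))
})

test_that("formatted report tables carry x/n counts and rendered intervals", {
  pm <- pm_from_rows(rbind(c(2, 1), c(3, 0), c(0, 0), c(0, 2)))
  oc <- marker_operating_characteristics(pm, c("c1", "c2"), c("c3", "c4"))
  fmt <- format_oc_table(oc)
  expect_equal(fmt$cases[1], "2/2")
  expect_equal(fmt$sens_ci[1], "--")
  sweep <- rule_sweep(c(2, 1), c(0, 1), ks = 1:3)
  fmt2 <- format_oc_table(sweep)
  expect_equal(fmt2$label, c("1 of 24", "2 of 24", "3 of 24"))
})
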