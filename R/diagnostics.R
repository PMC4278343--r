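#' Wald (normal-approximation) binomial confidence interval
#'
#' Computes `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, optionally widened
#' by the `1/(2n)` continuity correction on each side. Bounds are *not*
#' clipped to `[0, 1]` (report tables legitimately print upper bounds such
#' as 1.03). When the point estimate is exactly 0 or 1 the interval is
#' undefined (both bounds `NA`), rendered `"--"` by [format_ci()].
#'
#' The default is the uncorrected interval, which reproduces the published
#' validation-cohort intervals at two-decimal rounding; the corrected
#' variant is available via `continuity = TRUE`.
#'
#' @param successes number of successes (vectorised).
#' @param n number of trials (> 0).
#' @param alpha two-sided level (default 0.05 for 95% intervals).
#' @param continuity apply the 1/(2n) continuity correction.
#' @return numeric matrix with columns `lower`, `upper`; `NA` rows where the
#'   estimate is degenerate.
#' @export
#' @examples
#' wald_ci(33, 37)          # (0.79, 0.99) after rounding
#' wald_ci(36, 37)          # upper bound exceeds 1 (unclipped)
#' wald_ci(37, 37)          # undefined
wald_ci <- function(successes, n, alpha = 0.05, continuity = FALSE) {
  if (any(n == 0)) stop("n must be >= 1")
  stopifnot(all(successes >= 0), all(successes <= n))
  k <- max(length(successes), length(n))
  successes <- rep_len(successes, k)
  n <- rep_len(n, k)
  p <- successes / n
  z <- qnorm(1 - alpha / 2)
  half <- z * sqrt(p * (1 - p) / n) + if (continuity) 1 / (2 * n) else 0
  lower <- p - half
  upper <- p + half
  deg <- p %in% c(0, 1)
  lower[deg] <- NA_real_
  upper[deg] <- NA_real_
  cbind(lower = lower, upper = upper)
}

#' Round half away from zero
#'
#' Report-table rounding (0.005 -> 0.01), as opposed to R's banker's
#' rounding. Full precision is retained internally; rounding applies only to
#' rendered tables.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Render a confidence interval as in the report tables
#'
#' `"(0.79, 0.99)"`, or `"--"` for undefined (degenerate) intervals.
#' Rounding is half-up to two decimals. Following the report convention,
#' negative lower bounds are floored at 0.00 in rendering while upper bounds
#' are printed unclipped (1.01, 1.03); the raw [wald_ci()] bounds are never
#' truncated.
#'
#' @param lower,upper interval bounds (vectors; `NA` = undefined).
#' @export
format_ci <- function(lower, upper) {
  out <- sprintf("(%.2f, %.2f)", pmax(0, round_half_up(lower)),
                 round_half_up(upper))
  out[is.na(lower) | is.na(upper)] <- "--"
  out
}

#' Per-marker operating characteristics
#'
#' Sensitivity and specificity of each marker's presence/absence test, with
#' 95% Wald intervals. Sensitivity uses the case cores (one representative
#' core per case - cancer cores for the primary analysis, CCNC cores for the
#' field-effect analysis); specificity uses one representative core per
#' control. Denominators count non-missing cells per marker, so markers with
#' assays not run on some cores have reduced `n`.
#'
#' @param pm panel_matrix.
#' @param case_cores,control_cores character vectors of core ids.
#' @param alpha CI level.
#' @param continuity passed to [wald_ci()].
#' @return tibble with one row per marker in panel order: `marker`, `tp`,
#'   `n_case`, `sensitivity`, `sens_lower`, `sens_upper`, `tn`, `n_control`,
#'   `specificity`, `spec_lower`, `spec_upper`.
#' @export
marker_operating_characteristics <- function(pm, case_cores, control_cores,
                                             alpha = 0.05, continuity = FALSE) {
  if (length(case_cores) == 0 || length(control_cores) == 0) {
    stop("case and control selections must be non-empty")
  }
  case <- pm_subset(pm, cores = case_cores)
  ctrl <- pm_subset(pm, cores = control_cores)
  markers <- colnames(pm$call)
  tp <- colSums(case$call == 1L, na.rm = TRUE)
  n_case <- colSums(!is.na(case$call))
  tn <- colSums(ctrl$call == 0L, na.rm = TRUE)
  n_control <- colSums(!is.na(ctrl$call))
  empty <- n_case == 0 | n_control == 0
  if (any(empty)) {
    stop("marker(s) with all cells missing in a group: ",
         paste(markers[empty], collapse = ", "))
  }
  sens_ci <- wald_ci(tp, n_case, alpha, continuity)
  spec_ci <- wald_ci(tn, n_control, alpha, continuity)
  tibble::tibble(
    marker = markers,
    tp = as.integer(tp), n_case = as.integer(n_case),
    sensitivity = tp / n_case,
    sens_lower = sens_ci[, "lower"], sens_upper = sens_ci[, "upper"],
    tn = as.integer(tn), n_control = as.integer(n_control),
    specificity = tn / n_control,
    spec_lower = spec_ci[, "lower"], spec_upper = spec_ci[, "upper"]
  )
}

#' k-of-N composite rule operating characteristics
#'
#' Classifies a core positive when its methylated-marker count is at least
#' `k`, and reports sensitivity, specificity, PPV and NPV with Wald
#' intervals at the observed prevalence.
#'
#' @param case_counts,control_counts per-core marker counts
#'   ([count_positive_markers()]) for the case and control selections.
#' @param k positivity threshold, 1..24.
#' @param alpha,continuity passed to [wald_ci()].
#' @return one-row tibble: `k`, `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` and their CI bounds.
#' @export
k_of_n_rule <- function(case_counts, control_counts, k,
                        alpha = 0.05, continuity = FALSE) {
  stopifnot(k >= 1, k <= 24)
  tp <- sum(case_counts >= k)
  fn <- sum(case_counts < k)
  tn <- sum(control_counts < k)
  fp <- sum(control_counts >= k)
  sens_ci <- wald_ci(tp, tp + fn, alpha, continuity)
  spec_ci <- wald_ci(tn, tn + fp, alpha, continuity)
  ppv_ci <- if (tp + fp > 0) wald_ci(tp, tp + fp, alpha, continuity) else
    cbind(lower = NA_real_, upper = NA_real_)
  npv_ci <- if (tn + fn > 0) wald_ci(tn, tn + fn, alpha, continuity) else
    cbind(lower = NA_real_, upper = NA_real_)
  tibble::tibble(
    k = as.integer(k), tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = tp / (tp + fn),
    sens_lower = sens_ci[, "lower"], sens_upper = sens_ci[, "upper"],
    specificity = tn / (tn + fp),
    spec_lower = spec_ci[, "lower"], spec_upper = spec_ci[, "upper"],
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    ppv_lower = ppv_ci[, "lower"], ppv_upper = ppv_ci[, "upper"],
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    npv_lower = npv_ci[, "lower"], npv_upper = npv_ci[, "upper"]
  )
}

#' Sweep the k-of-N rule over thresholds
#'
#' @inheritParams k_of_n_rule
#' @param ks thresholds to evaluate (default 1..24). Sensitivity is
#'   non-increasing and specificity non-decreasing in `k` by construction.
#' @return tibble with one row per threshold.
#' @export
rule_sweep <- function(case_counts, control_counts, ks = 1:24,
                       alpha = 0.05, continuity = FALSE) {
  dplyr::bind_rows(lapply(ks, function(k)
    k_of_n_rule(case_counts, control_counts, k, alpha, continuity)))
}

#' Empirical ROC curve and AUC
#'
#' Builds the ROC curve of a score separating cases from controls. The AUC
#' is the Mann-Whitney probability that a random case outscores a random
#' control, ties counted one half; it equals the trapezoidal area under the
#' empirical curve. Curve points are evaluated at every distinct observed
#' score (threshold rule: positive if score >= threshold).
#'
#' @param case_scores,control_scores numeric score vectors (non-empty).
#' @param score_definition label recording how the score was built
#'   (`"count_only"`, `"count_then_level"`, `"level_mean"`, or free text).
#' @return object of class `roc_curve`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `score_definition`.
#' @export
roc_curve <- function(case_scores, control_scores,
                      score_definition = "count_only") {
  if (length(case_scores) == 0 || length(control_scores) == 0) {
    stop("both groups must be non-empty")
  }
  n1 <- length(case_scores)
  n0 <- length(control_scores)
  r <- rank(c(case_scores, control_scores))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(c(case_scores, control_scores)),
                            decreasing = TRUE))
  points <- tibble::tibble(
    threshold = thresholds,
    fpr = vapply(thresholds, function(t) mean(control_scores >= t), numeric(1)),
    tpr = vapply(thresholds, function(t) mean(case_scores >= t), numeric(1))
  )
  structure(list(points = points, auc = auc,
                 score_definition = score_definition),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve (%s): AUC = %.3f over %d thresholds\n",
              x$score_definition, x$auc, nrow(x$points)))
  invisible(x)
}

#' Per-core ROC scores from a panel matrix
#'
#' * `count_only`: number of methylated markers.
#' * `level_mean`: mean semi-quantitative level over non-missing markers.
#' * `count_then_level`: lexicographic count-then-mean-level, embedded as
#'   `count + mean_level / (1 + max_level)` with `max_level` the largest
#'   level observed across the supplied cores, so the level term only breaks
#'   count ties.
#'
#' @param pm panel_matrix.
#' @param cores core ids to score (default all).
#' @param definition score definition.
#' @return named numeric vector of scores.
#' @export
panel_scores <- function(pm, cores = NULL,
                         definition = c("count_then_level", "count_only",
                                        "level_mean")) {
  definition <- match.arg(definition)
  sub <- pm_subset(pm, cores = cores)
  counts <- count_positive_markers(sub)
  switch(definition,
    count_only = as.numeric(counts),
    level_mean = mean_methylation_level(sub),
    count_then_level = {
      ml <- mean_methylation_level(sub)
      max_level <- max(sub$level, 0, na.rm = TRUE)
      as.numeric(counts) + ml / (1 + max_level)
    }
  ) |> setNames(rownames(sub$call))
}

#' ROC curves for sequential marker combinations
#'
#' For an ordered marker list, computes one ROC curve per prefix (first
#' marker alone, first two, ...), scoring each core by its methylated-marker
#' count within the prefix with mean within-prefix level as tie-break. Used
#' to examine how sequentially adding markers commonly methylated in CCNC
#' cores improves discrimination.
#'
#' @param pm panel_matrix.
#' @param markers ordered character vector of marker names (subset of the
#'   panel).
#' @param case_cores,control_cores core id selections.
#' @return named list of `roc_curve` objects, one per prefix, named by the
#'   prefix's last marker.
#' @export
marker_combination_roc <- function(pm, markers, case_cores, control_cores) {
  unknown <- setdiff(markers, colnames(pm$call))
  if (length(unknown) > 0) {
    stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  }
  out <- lapply(seq_along(markers), function(len) {
    prefix <- markers[seq_len(len)]
    sub <- pm_subset(pm, markers = prefix)
    sc_case <- panel_scores(sub, case_cores, "count_then_level")
    sc_ctrl <- panel_scores(sub, control_cores, "count_then_level")
    roc_curve(sc_case, sc_ctrl,
              score_definition = paste0("count_then_level[",
                                        paste(prefix, collapse = "+"), "]"))
  })
  names(out) <- markers
  out
}

#' Report-shaped operating-characteristics table
#'
#' Renders marker and k-of-N rows the way the validation report prints them:
#' counts as `x/n`, estimates rounded half-up to two decimals, intervals as
#' `"(l, u)"` or `"--"` when degenerate.
#'
#' @param oc tibble from [marker_operating_characteristics()] (optionally
#'   with CCNC columns bound on) or [rule_sweep()].
#' @return tibble of formatted strings.
#' @export
format_oc_table <- function(oc) {
  if ("marker" %in% names(oc)) {
    tibble::tibble(
      label = oc$marker,
      cases = sprintf("%d/%d", oc$tp, oc$n_case),
      sensitivity = sprintf("%.2f", round_half_up(oc$sensitivity)),
      sens_ci = format_ci(oc$sens_lower, oc$sens_upper),
      controls = sprintf("%d/%d", oc$tn, oc$n_control),
      specificity = sprintf("%.2f", round_half_up(oc$specificity)),
      spec_ci = format_ci(oc$spec_lower, oc$spec_upper)
    )
  } else {
    tibble::tibble(
      label = sprintf("%d of 24", oc$k),
      cases = sprintf("%d/%d", oc$tp, oc$tp + oc$fn),
      sensitivity = sprintf("%.2f", round_half_up(oc$sensitivity)),
      sens_ci = format_ci(oc$sens_lower, oc$sens_upper),
      controls = sprintf("%d/%d", oc$tn, oc$tn + oc$fp),
      specificity = sprintf("%.2f", round_half_up(oc$specificity)),
      spec_ci = format_ci(oc$spec_lower, oc$spec_upper)
    )
  }
}
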