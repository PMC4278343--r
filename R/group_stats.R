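#' Within-case paired differences per marker
#'
#' For each marker, a paired t-test of methylation between each case's
#' cancer core and its representative non-cancer (CCNC) core. Pairs with a
#' missing value on either side are dropped for that marker. By default the
#' comparison is on semi-quantitative levels; `value = "call"` compares
#' binary calls instead.
#'
#' Degenerate inputs are handled without erroring so that simulations with
#' extreme configurations complete: if all within-pair differences are
#' identical, the t statistic is undefined and the result is flagged
#' (`p = 1` when the common difference is zero, `p = 0` otherwise).
#'
#' @param pm panel_matrix.
#' @param pairs tibble with columns `cancer_core`, `ccnc_core` (one row per
#'   case), e.g. built from [representative_cores()].
#' @param value `"level"` or `"call"`.
#' @param conf_level confidence level for the mean-difference interval.
#' @return tibble per marker: `marker`, `n_pairs`, `mean_cancer`,
#'   `mean_ccnc`, `difference` (cancer minus CCNC), `ci_lower`, `ci_upper`,
#'   `p_value`, `test`, `degenerate`.
#' @export
paired_marker_differences <- function(pm, pairs, value = c("level", "call"),
                                      conf_level = 0.95) {
  value <- match.arg(value)
  mat <- if (value == "level") pm$level else pm$call
  markers <- colnames(mat)
  rows <- lapply(markers, function(m) {
    a <- mat[pairs$cancer_core, m]
    b <- mat[pairs$ccnc_core, m]
    keep <- !is.na(a) & !is.na(b)
    a <- as.numeric(a[keep]); b <- as.numeric(b[keep])
    n <- length(a)
    base <- tibble::tibble(marker = m, n_pairs = n,
                           mean_cancer = NA_real_, mean_ccnc = NA_real_,
                           difference = NA_real_, ci_lower = NA_real_,
                           ci_upper = NA_real_, p_value = NA_real_,
                           test = "paired_t", degenerate = TRUE)
    if (n < 2) return(base)
    d <- a - b
    base$mean_cancer <- mean(a)
    base$mean_ccnc <- mean(b)
    base$difference <- mean(d)
    if (sd(d) == 0) {
      base$ci_lower <- mean(d)
      base$ci_upper <- mean(d)
      base$p_value <- if (mean(d) == 0) 1 else 0
      return(base)
    }
    tt <- t.test(a, b, paired = TRUE, conf.level = conf_level)
    base$ci_lower <- tt$conf.int[1]
    base$ci_upper <- tt$conf.int[2]
    base$p_value <- tt$p.value
    base$degenerate <- FALSE
    base
  })
  dplyr::bind_rows(rows)
}

#' Welch comparison of per-core marker counts between two groups
#'
#' Two-sample t-test with unequal variances on methylation burden (marker
#' counts or levels) between independent groups of cores, e.g. CCNC versus
#' control cores, or abnormal cores from cases versus controls. Reports
#' group means, the mean difference `a - b`, its confidence interval and
#' p-value.
#'
#' If both groups have zero variance the Welch statistic is undefined; the
#' result is flagged degenerate (`p = 1` for equal means, `p = 0`
#' otherwise) rather than erroring.
#'
#' @param counts_a,counts_b numeric vectors (length >= 2 each).
#' @param labels length-2 character naming the groups.
#' @param conf_level confidence level.
#' @return one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `difference`, `ci_lower`, `ci_upper`, `p_value`, `test`,
#'   `degenerate`.
#' @export
compare_group_counts <- function(counts_a, counts_b,
                                 labels = c("a", "b"), conf_level = 0.95) {
  if (length(counts_a) < 2 || length(counts_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  base <- tibble::tibble(
    group_a = labels[1], group_b = labels[2],
    n_a = length(counts_a), n_b = length(counts_b),
    mean_a = mean(counts_a), mean_b = mean(counts_b),
    difference = mean(counts_a) - mean(counts_b),
    ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
    test = "welch_t", degenerate = TRUE
  )
  if (var(counts_a) == 0 && var(counts_b) == 0) {
    base$ci_lower <- base$difference
    base$ci_upper <- base$difference
    base$p_value <- if (base$difference == 0) 1 else 0
    return(base)
  }
  tt <- t.test(counts_a, counts_b, var.equal = FALSE, conf.level = conf_level)
  base$ci_lower <- tt$conf.int[1]
  base$ci_upper <- tt$conf.int[2]
  base$p_value <- tt$p.value
  base$degenerate <- FALSE
  base
}

#' Association between methylation burden and age, per stratum
#'
#' Ordinary least-squares regression of per-core (or per-patient) marker
#' counts on age, fitted separately within a disease stratum: the slope is
#' the average change in methylated-marker count per year of patient age (or
#' core age since processing).
#'
#' @param counts numeric response (marker counts).
#' @param ages numeric predictor, same length.
#' @param stratum label (`"cases"`, `"controls"`, ...), recorded in the
#'   output.
#' @param predictor label (`"patient_age"` or `"core_age"`).
#' @param conf_level confidence level.
#' @return one-row tibble: `stratum`, `predictor`, `n`, `slope`, `ci_lower`,
#'   `ci_upper`, `p_value`.
#' @export
age_association <- function(counts, ages, stratum = "cases",
                            predictor = "patient_age", conf_level = 0.95) {
  keep <- is.finite(counts) & is.finite(ages)
  counts <- counts[keep]; ages <- ages[keep]
  if (length(counts) < 3) stop("need at least 3 complete (count, age) pairs")
  fit <- lm(counts ~ ages)
  ci <- suppressWarnings(confint(fit, "ages", level = conf_level))
  # exact linear inputs trigger R's perfect-fit warning; the slope/CI are valid
  p <- suppressWarnings(summary(fit)$coefficients["ages", "Pr(>|t|)"])
  tibble::tibble(stratum = stratum, predictor = predictor,
                 n = length(counts),
                 slope = unname(coef(fit)["ages"]),
                 ci_lower = ci[1], ci_upper = ci[2], p_value = p)
}
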