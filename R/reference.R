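#' Published validation counts for the 24-marker panel
#'
#' Per-marker and k-of-24 rule counts from the panel's validation cohort of
#' 37 prostate-cancer cases and 67 controls with elevated PSA: number of
#' positive cancer cores (one representative cancer core per case), number of
#' negative control cores (the most-methylated core per control), and number
#' of positive CCNC cores (the most-methylated non-cancer core per case).
#' Denominators below the cohort sizes reflect assays that were not run on
#' every core. The `*_ci` columns carry the published 95% interval rendering
#' ("--" where the point estimate is 0 or 1), which the uncorrected Wald
#' interval reproduces at two-decimal rounding.
#'
#' These counts anchor the synthetic-cohort tissue profiles
#' ([default_profiles()]) and serve as fixtures for interval-construction
#' checks.
#'
#' @param kind `"marker"` for the 24 per-marker rows, `"rule"` for the
#'   k-of-24 composite rule rows (k = 3..20), or `"all"`.
#' @return A tibble with columns `label`, `kind`, `k` (NA for markers),
#'   `cancer_pos`, `cancer_n`, `cancer_ci`, `control_neg`, `control_n`,
#'   `control_ci`, `ccnc_pos`, `ccnc_n`, `ccnc_ci`.
#' @export
reference_panel_counts <- function(kind = c("all", "marker", "rule")) {
  kind <- match.arg(kind)
  m <- function(label, cp, cn, cci, sp, sn, sci, np, nn, nci) {
    tibble::tibble(label = label, kind = "marker", k = NA_integer_,
                   cancer_pos = cp, cancer_n = cn, cancer_ci = cci,
                   control_neg = sp, control_n = sn, control_ci = sci,
                   ccnc_pos = np, ccnc_n = nn, ccnc_ci = nci)
  }
  markers <- dplyr::bind_rows(
    m("CYBA",     22, 37, "(0.44, 0.75)", 64, 67, "(0.91, 1.00)",  5, 37, "(0.02, 0.25)"),
    m("HOXB5",    31, 37, "(0.72, 0.96)", 56, 67, "(0.75, 0.92)", 24, 36, "(0.51, 0.82)"),
    m("RASSF1",   33, 37, "(0.79, 0.99)", 55, 67, "(0.73, 0.91)", 16, 37, "(0.27, 0.59)"),
    m("SOCS3",    27, 37, "(0.59, 0.87)", 61, 67, "(0.84, 0.98)", 17, 36, "(0.31, 0.64)"),
    m("GRASP",    22, 37, "(0.44, 0.75)", 64, 67, "(0.91, 1.00)",  1, 37, "(0.00, 0.08)"),
    m("HAPLN3",   27, 37, "(0.59, 0.87)", 63, 67, "(0.88, 1.00)", 11, 37, "(0.15, 0.44)"),
    m("SLC16A5",  11, 37, "(0.15, 0.44)", 64, 67, "(0.91, 1.00)",  2, 37, "(0.00, 0.13)"),
    m("HOXD9",    34, 37, "(0.83, 1.01)", 43, 65, "(0.55, 0.78)", 29, 36, "(0.68, 0.93)"),
    m("ARHGEF10",  8, 37, "(0.08, 0.35)", 62, 67, "(0.86, 0.99)",  7, 37, "(0.06, 0.32)"),
    m("KLK10",    14, 37, "(0.22, 0.53)", 67, 67, "--",            1, 37, "(0.00, 0.08)"),
    m("GSTP1",    25, 36, "(0.54, 0.84)", 64, 67, "(0.91, 1.00)", 10, 37, "(0.13, 0.41)"),
    m("RASSF5",   28, 37, "(0.62, 0.90)", 61, 67, "(0.84, 0.98)", 21, 37, "(0.41, 0.73)"),
    m("MOXD1",    12, 37, "(0.17, 0.48)", 61, 67, "(0.84, 0.98)",  6, 37, "(0.04, 0.28)"),
    m("RARB",     25, 37, "(0.52, 0.83)", 64, 67, "(0.91, 1.00)",  4, 37, "(0.01, 0.21)"),
    m("GPX7",     16, 37, "(0.27, 0.59)", 64, 67, "(0.91, 1.00)",  5, 37, "(0.02, 0.25)"),
    m("APC",      27, 36, "(0.61, 0.89)", 61, 67, "(0.84, 0.98)", 12, 35, "(0.19, 0.50)"),
    m("GFRA2",    13, 36, "(0.20, 0.52)", 64, 67, "(0.91, 1.00)",  5, 35, "(0.03, 0.26)"),
    m("LOXL2",    11, 36, "(0.16, 0.46)", 65, 67, "(0.93, 1.00)",  5, 35, "(0.03, 0.26)"),
    m("NEUROG3",  18, 36, "(0.34, 0.66)", 64, 67, "(0.91, 1.00)",  6, 35, "(0.05, 0.30)"),
    m("PTGS2",     4, 36, "(0.01, 0.21)", 65, 67, "(0.93, 1.00)", 10, 35, "(0.14, 0.44)"),
    m("ADCY4",    36, 37, "(0.92, 1.03)", 56, 67, "(0.75, 0.92)", 20, 37, "(0.38, 0.70)"),
    m("CXCL14",   27, 37, "(0.59, 0.87)", 63, 67, "(0.88, 1.00)", 10, 37, "(0.13, 0.41)"),
    m("HEMK1",    15, 37, "(0.25, 0.56)", 60, 67, "(0.82, 0.97)",  2, 37, "(0.00, 0.13)"),
    m("KIFC2",    22, 37, "(0.44, 0.75)", 67, 67, "--",            8, 37, "(0.08, 0.35)")
  )
  r <- function(k, cp, cci, sp, sci, np, nci) {
    tibble::tibble(label = paste0(k, " of 24"), kind = "rule", k = as.integer(k),
                   cancer_pos = cp, cancer_n = 37, cancer_ci = cci,
                   control_neg = sp, control_n = 67, control_ci = sci,
                   ccnc_pos = np, ccnc_n = 37, ccnc_ci = nci)
  }
  rules <- dplyr::bind_rows(
    r(3, 37, "--",            46, "(0.58, 0.80)", 31, "(0.72, 0.96)"),
    r(4, 37, "--",            56, "(0.75, 0.92)", 23, "(0.47, 0.78)"),
    r(5, 37, "--",            65, "(0.93, 1.01)", 23, "(0.47, 0.78)"),
    r(6, 36, "(0.92, 1.03)",  66, "(0.96, 1.01)", 19, "(0.35, 0.67)"),
    r(7, 36, "(0.92, 1.03)",  66, "(0.96, 1.01)", 18, "(0.33, 0.65)"),
    r(8, 36, "(0.92, 1.03)",  67, "--",           15, "(0.25, 0.56)"),
    r(9, 35, "(0.87, 1.02)",  67, "--",           11, "(0.15, 0.44)"),
    r(10, 30, "(0.68, 0.94)", 67, "--",           11, "(0.15, 0.44)"),
    r(11, 27, "(0.59, 0.87)", 67, "--",            5, "(0.02, 0.25)"),
    r(12, 25, "(0.52, 0.83)", 67, "--",            5, "(0.02, 0.25)"),
    r(13, 20, "(0.38, 0.70)", 67, "--",            3, "(0.00, 0.17)"),
    r(14, 17, "(0.30, 0.62)", 67, "--",            2, "(0.00, 0.13)"),
    r(15, 15, "(0.25, 0.56)", 67, "--",            1, "(0.00, 0.08)"),
    r(16, 14, "(0.22, 0.53)", 67, "--",            0, "--"),
    r(17, 11, "(0.15, 0.44)", 67, "--",            0, "--"),
    r(18,  7, "(0.06, 0.32)", 67, "--",            0, "--"),
    r(19,  7, "(0.06, 0.32)", 67, "--",            0, "--"),
    r(20,  3, "(0.00, 0.17)", 67, "--",            0, "--")
  )
  out <- switch(kind, all = dplyr::bind_rows(markers, rules),
                marker = markers, rule = rules)
  out
}
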