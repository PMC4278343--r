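# Shared fixtures: tiny panels, in-memory Cq tables, and small panel
# matrices built by hand so expected values can be enumerated.

tiny_panel <- function(cutoff = 35) {
  tibble::tibble(
    assay_id = c("a1", "a2", "d_A", "d_B"),
    marker = c("m1", "m2", "m3", "m3"),
    cq_cutoff = cutoff
  )
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A panel_matrix from explicit call/level rows (NA = missing cell).
pm_from_rows <- function(levels, markers = NULL, cores = NULL) {
  level <- as.matrix(levels)
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(level)))
  if (is.null(cores)) cores <- paste0("c", seq_len(nrow(level)))
  dimnames(level) <- list(cores, markers)
  call <- ifelse(is.na(level), NA_integer_, as.integer(level > 0))
  panel_matrix(call = call, level = level)
}

# Deterministic small synthetic cohort for integration-style tests.
small_cohort <- function(seed = 42, n_controls = 20, n_cases = 12) {
  generate_cohort(cohort_config(n_controls = n_controls, n_cases = n_cases,
                                seed = seed))
}

# Brute-force Mann-Whitney AUC: all case/control pairs, ties one half.
brute_force_auc <- function(case_scores, control_scores) {
  wins <- outer(case_scores, control_scores, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(wins)
}
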