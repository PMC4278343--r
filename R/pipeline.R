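#' Default pipeline configuration
#'
#' A single configuration drives every stage of the pipeline. Fields:
#' `seed` (integer, all randomness), `stages` (subset of `simulate`, `call`,
#' `diagnostics`, `groupstats`, `select_models`), `k` (composite-rule
#' threshold, 1..24), `mode` (`cancer` or `ccnc` sensitivity analysis),
#' `continuity` (Wald CI continuity correction), `covariate_mode`
#' (`indicator`/`level` for model selection), `max_size`, `include_age`,
#' `n_controls`, `n_cases`, `rho` (generator), and optional `cq_matrix` /
#' `sample_sheet` paths replacing the simulate stage.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  config <- list(
    seed = 1L,
    stages = c("simulate", "call", "diagnostics", "groupstats", "select_models"),
    k = 5L, mode = "cancer", continuity = FALSE,
    covariate_mode = "indicator", max_size = 3L, include_age = FALSE,
    n_controls = 67L, n_cases = 37L, rho = 0,
    cq_matrix = NULL, sample_sheet = NULL
  )
  validate_pipeline_config(modifyList(config, list(...)))
}

#' @rdname pipeline_config
#' @param config configuration list (or a YAML file path in
#'   [run_pipeline()]).
#' @export
validate_pipeline_config <- function(config) {
  known_stages <- c("simulate", "call", "diagnostics", "groupstats",
                    "select_models")
  bad <- setdiff(config$stages, known_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(config$k) || config$k < 1 || config$k > 24) {
    stop("field 'k' must lie in 1..24")
  }
  if (!config$mode %in% c("cancer", "ccnc")) {
    stop("field 'mode' must be 'cancer' or 'ccnc'")
  }
  if (!config$covariate_mode %in% c("indicator", "level")) {
    stop("field 'covariate_mode' must be 'indicator' or 'level'")
  }
  if (!is.numeric(config$seed)) stop("field 'seed' must be an integer")
  if (!is.numeric(config$rho) || config$rho < 0 || config$rho >= 1) {
    stop("field 'rho' must lie in [0, 1)")
  }
  config
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order - simulate (or load)
#' the cohort, call and pool methylation, per-marker and k-of-N diagnostics,
#' group comparisons, best-subsets model selection - writing one CSV per
#' result table plus a run manifest (`manifest.json`) recording the seed,
#' configuration digest, input/output file digests and package version.
#' Reruns with an identical configuration produce byte-identical outputs.
#'
#' @param config configuration list from [pipeline_config()] or a YAML file
#'   path.
#' @param outdir output directory (created if needed).
#' @return the output directory, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (is.character(config)) {
    config <- validate_pipeline_config(
      modifyList(pipeline_config(), yaml::read_yaml(config)))
  } else {
    config <- validate_pipeline_config(modifyList(pipeline_config(), config))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  panel <- default_panel()
  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    readr::write_csv(df, path)
    outputs <<- c(outputs, name)
    path
  }
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] seed=%d %s", stage, config$seed,
                    paste(sprintf("%s", c(...)), collapse = " ")))
  }

  # --- inputs: simulate or load ---
  if (!is.null(config$cq_matrix)) {
    if (!file.exists(config$cq_matrix) || !file.exists(config$sample_sheet)) {
      stop("input file not found: ",
           c(config$cq_matrix, config$sample_sheet)[
             !file.exists(c(config$cq_matrix, config$sample_sheet))][1])
    }
    cq <- read_cq_matrix(config$cq_matrix, panel)
    samples <- read_sample_sheet(config$sample_sheet)
    log_stage("load", sprintf("cores=%d", nrow(samples)))
  } else {
    cohort <- generate_cohort(cohort_config(
      n_controls = config$n_controls, n_cases = config$n_cases,
      seed = config$seed, rho = config$rho), panel)
    cq <- cohort$cq
    samples <- cohort$samples
    if ("simulate" %in% config$stages) {
      emit(samples, "samples.csv")
      write_cq_matrix(cq, file.path(outdir, "cq_matrix.csv"))
      outputs <- c(outputs, "cq_matrix.csv")
    }
    log_stage("simulate", sprintf("patients=%d cores=%d",
                                  length(unique(samples$patient_id)), nrow(samples)))
  }

  pm <- build_panel_matrix(cq, panel)
  if ("call" %in% config$stages) {
    write_panel_matrix(pm, file.path(outdir, "panel_matrix.csv"))
    outputs <- c(outputs, "panel_matrix.csv")
    log_stage("call", sprintf("cells=%d missing=%d",
                              length(pm$call), sum(is.na(pm$call))))
  }

  ctrl <- representative_cores(pm, samples, "control_best")
  cancer <- representative_cores(pm, samples, "case_cancer")
  ccnc <- suppressMessages(representative_cores(pm, samples, "case_ccnc"))
  case_sel <- if (config$mode == "cancer") cancer else ccnc

  if ("diagnostics" %in% config$stages) {
    oc <- marker_operating_characteristics(pm, case_sel$core_id, ctrl$core_id,
                                           continuity = config$continuity)
    emit(oc, "marker_oc.csv")
    emit(format_oc_table(oc), "marker_oc_formatted.csv")
    case_counts <- count_positive_markers(pm_subset(pm, case_sel$core_id))
    ctrl_counts <- count_positive_markers(pm_subset(pm, ctrl$core_id))
    sweep <- rule_sweep(case_counts, ctrl_counts, continuity = config$continuity)
    emit(sweep, "rule_sweep.csv")
    roc <- roc_curve(panel_scores(pm, case_sel$core_id),
                     panel_scores(pm, ctrl$core_id), "count_then_level")
    emit(tibble::tibble(auc = roc$auc), "roc_auc.csv")
    emit(roc$points, "roc_points.csv")
    log_stage("diagnostics", sprintf("k=%d cases=%d controls=%d auc=%.3f",
                                     config$k, nrow(case_sel), nrow(ctrl), roc$auc))
  }

  if ("groupstats" %in% config$stages) {
    counts <- count_positive_markers(pm)
    is_ctrl_core <- samples$status == "control"
    is_ccnc_core <- samples$status == "case" & samples$histology != "cancer"
    cmp <- compare_group_counts(counts[samples$core_id[is_ccnc_core]],
                                counts[samples$core_id[is_ctrl_core]],
                                labels = c("ccnc_cores", "control_cores"))
    pairs <- dplyr::inner_join(cancer, ccnc, by = "patient_id",
                               suffix = c("_cancer", "_ccnc"))
    names(pairs)[names(pairs) == "core_id_cancer"] <- "cancer_core"
    names(pairs)[names(pairs) == "core_id_ccnc"] <- "ccnc_core"
    paired <- paired_marker_differences(pm, pairs)
    emit(cmp, "group_comparison.csv")
    emit(paired, "paired_differences.csv")
    if ("age" %in% names(samples)) {
      pat <- samples[!duplicated(samples$patient_id), ]
      rep_all <- rbind(ctrl, cancer)
      rep_all$status <- pat$status[match(rep_all$patient_id, pat$patient_id)]
      rep_all$age <- pat$age[match(rep_all$patient_id, pat$patient_id)]
      rep_all$count <- counts[rep_all$core_id]
      assoc <- dplyr::bind_rows(lapply(c("control", "case"), function(s) {
        sub <- rep_all[rep_all$status == s, ]
        age_association(sub$count, sub$age,
                        stratum = if (s == "case") "cases" else "controls")
      }))
      emit(assoc, "age_association.csv")
    }
    log_stage("groupstats", sprintf("pairs=%d", nrow(pairs)))
  }

  if ("select_models" %in% config$stages) {
    pat <- samples[!duplicated(samples$patient_id), ]
    units <- rbind(ctrl, cancer)
    units$status <- pat$status[match(units$patient_id, pat$patient_id)]
    units$age <- if ("age" %in% names(pat))
      pat$age[match(units$patient_id, pat$patient_id)] else NULL
    split <- split_cohort(units$status, seed = config$seed)
    x <- model_covariates(pm, units$core_id, mode = config$covariate_mode,
                          age = units$age)
    y <- as.integer(units$status == "case")
    ranking <- best_subsets(x[split$train, , drop = FALSE], y[split$train],
                            max_size = config$max_size,
                            mode = config$covariate_mode,
                            include_age = config$include_age,
                            seed = config$seed)
    top <- top_models(ranking)
    top$test_auc <- vapply(top$coefficients, evaluate_frozen,
                           numeric(1), x[split$test, , drop = FALSE],
                           y[split$test])
    emit(top[, c("rank", "covariates", "size", "mode", "cv_auc", "test_auc")],
         "top_models.csv")
    emit(ranking[, c("rank", "covariates", "size", "mode", "cv_auc", "converged")],
         "model_ranking.csv")
    coefs <- lapply(seq_len(nrow(top)), function(i)
      list(covariates = top$covariates[i], coefficients = as.list(top$coefficients[[i]])))
    jsonlite::write_json(coefs, file.path(outdir, "top_model_coefficients.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "top_model_coefficients.json")
    log_stage("select_models", sprintf("subsets=%d train=%d test=%d",
                                       nrow(ranking), length(split$train),
                                       length(split$test)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("methpanel")),
    seed = config$seed,
    config = config[setdiff(names(config), c("cq_matrix", "sample_sheet"))],
    config_digest = unname(md5sum_text(
      jsonlite::toJSON(config, auto_unbox = TRUE, null = "null"))),
    input_digests = if (!is.null(config$cq_matrix))
      as.list(md5sum(c(config$cq_matrix, config$sample_sheet))) else NULL,
    outputs = setNames(as.list(unname(md5sum(file.path(outdir, outputs)))),
                       outputs)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

md5sum_text <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(x), tmp)
  md5sum(tmp)
}
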