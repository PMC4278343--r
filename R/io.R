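#' Read a Cq matrix
#'
#' Reads a CSV/TSV of MS-qPCR cycle thresholds: first column `core_id`, one
#' further column per assay (header = assay id). Cell semantics: a positive
#' number is the observed Cq; an empty cell or `NA` means the reaction gave
#' no amplification (a negative observation, not missing data); the sentinel
#' `NR` means the assay was not run on that core (missing). Assays in the
#' panel but absent from the file are missing for every core.
#'
#' In the returned tibble no-amplification is `NA` and not-run is `NaN`
#' (distinguishable with `is.nan()`); downstream calling treats them as
#' call 0 and missing respectively.
#'
#' @param path CSV or TSV file (delimiter inferred from extension, `.tsv` =
#'   tab).
#' @param panel panel tibble ([default_panel()]); columns not matching a
#'   panel assay id are an error.
#' @return tibble with `core_id` and one numeric column per assay present in
#'   the file.
#' @export
read_cq_matrix <- function(path, panel = default_panel()) {
  validate_panel(panel)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), show_col_types = FALSE)
  if (!"core_id" %in% names(raw)) {
    names(raw)[1] <- "core_id"
  }
  assay_cols <- setdiff(names(raw), "core_id")
  unknown <- setdiff(assay_cols, panel$assay_id)
  if (length(unknown) > 0) {
    stop("unknown assay id column(s) not in panel: ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(raw$core_id)) {
    stop("duplicate core_id: ",
         paste(unique(raw$core_id[duplicated(raw$core_id)]), collapse = ", "))
  }
  parse_cell <- function(x, col) {
    x <- trimws(x)
    out <- rep(NA_real_, length(x))
    out[x == "NR"] <- NaN
    num_idx <- !(x %in% c("", "NA", "NR"))
    if (any(num_idx)) {
      val <- suppressWarnings(as.numeric(x[num_idx]))
      bad <- is.na(val)
      if (any(bad)) {
        stop(sprintf("non-numeric Cq value '%s' in column '%s', row %d",
                     x[num_idx][bad][1], col, which(num_idx)[bad][1]))
      }
      if (any(val <= 0)) {
        stop(sprintf("nonpositive Cq value %s in column '%s', row %d",
                     val[val <= 0][1], col, which(num_idx)[val <= 0][1]))
      }
      out[num_idx] <- val
    }
    out
  }
  for (col in assay_cols) raw[[col]] <- parse_cell(raw[[col]], col)
  raw
}

#' Write a Cq matrix
#'
#' Inverse of [read_cq_matrix()]: no-amplification (`NA`) is written as an
#' empty cell, not-run (`NaN`) as `NR`.
#'
#' @param cq tibble as returned by [read_cq_matrix()] or [generate_cohort()].
#' @param path output CSV path.
#' @export
write_cq_matrix <- function(cq, path) {
  out <- cq
  for (col in setdiff(names(out), "core_id")) {
    x <- out[[col]]
    chr <- ifelse(is.nan(x), "NR", ifelse(is.na(x), "", sprintf("%.10g", x)))
    out[[col]] <- chr
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Convert Cq values to per-assay methylation calls and levels
#'
#' A reaction is called methylated when its Cq lies strictly below the
#' assay's cutoff (default 35 cycles). The semi-quantitative level is
#' `max(0, cutoff - Cq)`: cycles of amplification advantage over the cutoff,
#' a monotone proxy for methylated-template abundance (more template, earlier
#' amplification, larger level). No amplification gives call 0, level 0;
#' assays not run are missing.
#'
#' @param cq wide Cq tibble (see [read_cq_matrix()]).
#' @param panel panel tibble; assays in the panel absent from `cq` are
#'   reported missing.
#' @return long tibble: `core_id`, `assay_id`, `call` (0/1), `level`
#'   (>= 0), `missing` (logical). `call` and `level` are `NA` where missing.
#' @export
call_methylation <- function(cq, panel = default_panel()) {
  validate_panel(panel)
  assay_cols <- setdiff(names(cq), "core_id")
  unknown <- setdiff(assay_cols, panel$assay_id)
  if (length(unknown) > 0) {
    stop("unknown assay id(s): ", paste(unknown, collapse = ", "))
  }
  cutoff <- setNames(panel$cq_cutoff, panel$assay_id)
  res <- lapply(panel$assay_id, function(a) {
    if (a %in% assay_cols) {
      x <- cq[[a]]
      missing <- is.nan(x)
      call <- ifelse(missing, NA_integer_,
                     ifelse(!is.na(x) & x < cutoff[[a]], 1L, 0L))
      level <- ifelse(missing, NA_real_,
                      ifelse(!is.na(x), pmax(0, cutoff[[a]] - x), 0))
      level[!is.na(call) & call == 0L] <- 0
    } else {
      missing <- rep(TRUE, nrow(cq))
      call <- rep(NA_integer_, nrow(cq))
      level <- rep(NA_real_, nrow(cq))
    }
    tibble::tibble(core_id = cq$core_id, assay_id = a,
                   call = call, level = level, missing = missing)
  })
  dplyr::bind_rows(res)
}

#' Pool dual assays into per-marker calls
#'
#' Markers covered by two assays are pooled: the marker call is the logical
#' OR of the assay calls, the marker level is the maximum assay level, and
#' the marker is missing only when all of its assays are missing.
#' Single-assay markers pass through unchanged.
#'
#' @param assay_calls long tibble from [call_methylation()].
#' @param panel panel tibble.
#' @return A [panel_matrix] over the panel's 24 markers.
#' @export
pool_assays <- function(assay_calls, panel = default_panel()) {
  validate_panel(panel)
  marker_of <- setNames(panel$marker, panel$assay_id)
  df <- assay_calls
  df$marker <- marker_of[df$assay_id]
  pooled <- df |>
    dplyr::group_by(.data$core_id, .data$marker) |>
    dplyr::summarise(
      missing = all(.data$missing),
      call = if (all(.data$missing)) NA_integer_ else
        as.integer(any(.data$call == 1L, na.rm = TRUE)),
      level = if (all(.data$missing)) NA_real_ else
        max(.data$level, 0, na.rm = TRUE),
      .groups = "drop"
    )
  cores <- unique(assay_calls$core_id)
  markers <- unique(panel$marker)
  to_matrix <- function(value, mode) {
    m <- matrix(if (mode == "integer") NA_integer_ else NA_real_,
                nrow = length(cores), ncol = length(markers),
                dimnames = list(cores, markers))
    m[cbind(match(pooled$core_id, cores), match(pooled$marker, markers))] <-
      pooled[[value]]
    m
  }
  panel_matrix(call = to_matrix("call", "integer"),
               level = to_matrix("level", "double"))
}

#' Construct a panel matrix
#'
#' A `panel_matrix` holds, for each core x marker cell, the binary
#' methylation call and the nonnegative semi-quantitative level; `NA` cells
#' are missing (assay(s) not run) and are excluded from all denominators.
#' Invariant: on non-missing cells, `call == 1` exactly when `level > 0`.
#'
#' @param call integer matrix (cores x markers) of 0/1 calls, `NA` = missing.
#' @param level numeric matrix of the same shape, levels >= 0.
#' @return object of class `panel_matrix`.
#' @export
panel_matrix <- function(call, level) {
  stopifnot(is.matrix(call), is.matrix(level),
            identical(dim(call), dim(level)),
            identical(dimnames(call), dimnames(level)))
  miss_mismatch <- xor(is.na(call), is.na(level))
  if (any(miss_mismatch)) stop("call and level must share the same missing cells")
  ok <- !is.na(call)
  if (any(call[ok] == 1L & level[ok] <= 0) || any(call[ok] == 0L & level[ok] != 0)) {
    stop("invariant violated: call = 1 must coincide with level > 0")
  }
  if (any(level[ok] < 0)) stop("levels must be nonnegative")
  structure(list(call = call, level = level), class = "panel_matrix")
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat(sprintf("panel_matrix: %d cores x %d markers (%d missing cells)\n",
              nrow(x$call), ncol(x$call), sum(is.na(x$call))))
  counts <- count_positive_markers(x)
  cat(sprintf("marker counts per core: min %s, median %s, max %s\n",
              min(counts), stats::median(counts), max(counts)))
  invisible(x)
}

#' Subset a panel matrix by cores and/or markers
#'
#' @param pm panel_matrix.
#' @param cores core ids (or indices) to keep; NULL keeps all.
#' @param markers marker names to keep; NULL keeps all.
#' @return panel_matrix.
#' @export
pm_subset <- function(pm, cores = NULL, markers = NULL) {
  ci <- if (is.null(cores)) seq_len(nrow(pm$call)) else cores
  mi <- if (is.null(markers)) seq_len(ncol(pm$call)) else markers
  if (is.character(mi) && !all(mi %in% colnames(pm$call))) {
    stop("unknown marker(s): ",
         paste(setdiff(mi, colnames(pm$call)), collapse = ", "))
  }
  if (is.character(ci) && !all(ci %in% rownames(pm$call))) {
    stop("unknown core(s): ", paste(setdiff(ci, rownames(pm$call)), collapse = ", "))
  }
  panel_matrix(call = pm$call[ci, mi, drop = FALSE],
               level = pm$level[ci, mi, drop = FALSE])
}

#' Build a panel matrix from a Cq table
#'
#' Convenience wrapper: [call_methylation()] then [pool_assays()].
#'
#' @inheritParams call_methylation
#' @return panel_matrix.
#' @export
build_panel_matrix <- function(cq, panel = default_panel()) {
  pool_assays(call_methylation(cq, panel), panel)
}

#' Write / read a panel matrix as tidy CSV
#'
#' Long form, bit-stable column and row order: `core_id`, `marker`, `call`,
#' `level`, `missing`; cores in matrix order, markers in panel order within
#' core. Missing cells have empty `call`/`level` and `missing = TRUE`.
#'
#' @param pm panel_matrix.
#' @param path CSV path.
#' @export
write_panel_matrix <- function(pm, path) {
  long <- tibble::tibble(
    core_id = rep(rownames(pm$call), each = ncol(pm$call)),
    marker = rep(colnames(pm$call), times = nrow(pm$call)),
    call = as.integer(t(pm$call)),
    level = as.numeric(t(pm$level)),
    missing = is.na(as.integer(t(pm$call)))
  )
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_panel_matrix
#' @export
read_panel_matrix <- function(path) {
  long <- readr::read_csv(path, col_types = readr::cols(
    core_id = "c", marker = "c", call = "i", level = "d", missing = "l"))
  cores <- unique(long$core_id)
  markers <- unique(long$marker)
  call <- matrix(NA_integer_, length(cores), length(markers),
                 dimnames = list(cores, markers))
  level <- matrix(NA_real_, length(cores), length(markers),
                  dimnames = list(cores, markers))
  idx <- cbind(match(long$core_id, cores), match(long$marker, markers))
  call[idx] <- long$call
  level[idx] <- long$level
  panel_matrix(call, level)
}

#' Count positive markers per core
#'
#' The per-core methylation burden: number of markers called methylated,
#' summed over non-missing cells only (range 0..24 on the full panel).
#'
#' @param pm panel_matrix.
#' @return named integer vector, one element per core.
#' @export
count_positive_markers <- function(pm) {
  counts <- rowSums(pm$call == 1L, na.rm = TRUE)
  storage.mode(counts) <- "integer"
  counts
}

#' Mean methylation level per core
#'
#' Mean of the semi-quantitative levels over non-missing markers (zeros for
#' unmethylated markers included), used as a tie-breaker and as the
#' level-based ROC score.
#'
#' @param pm panel_matrix.
#' @return named numeric vector.
#' @export
mean_methylation_level <- function(pm) {
  rowMeans(pm$level, na.rm = TRUE)
}

#' Select the representative core among a patient's cores
#'
#' Picks the core with the highest number of methylated markers; ties are
#' broken by higher mean level, then by input order (stable). This mirrors
#' the reporting convention of using each control's most-methylated core and
#' each case's most-methylated non-cancer core, so that no patient is
#' represented twice in operating-characteristic denominators.
#'
#' @param pm panel_matrix containing (at least) the candidate cores.
#' @param core_ids candidate core ids, in a stable order.
#' @return the selected core id (length-1 character).
#' @export
select_representative_core <- function(pm, core_ids) {
  if (length(core_ids) == 0) stop("no candidate cores")
  sub <- pm_subset(pm, cores = core_ids)
  counts <- count_positive_markers(sub)
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    lv <- mean_methylation_level(sub)[best]
    best <- best[lv == max(lv)]
  }
  core_ids[best[1]]
}

#' Representative cores per patient for a given analysis role
#'
#' Applies [select_representative_core()] patient-wise:
#' * `control_best` - each control's most-methylated core;
#' * `case_ccnc` - each case's most-methylated non-cancer (CCNC) core,
#'   cancer cores excluded before selection; cases with no non-cancer core
#'   are dropped (reported in the `dropped` attribute);
#' * `case_cancer` - each case's cancer core (most-methylated one if the
#'   case contributed more than one cancer core).
#'
#' @param pm panel_matrix.
#' @param samples sample sheet tibble ([read_sample_sheet()]).
#' @param role one of `"control_best"`, `"case_ccnc"`, `"case_cancer"`.
#' @return tibble `patient_id`, `core_id`; attribute `dropped` lists case
#'   patients with no eligible core.
#' @export
representative_cores <- function(pm, samples,
                                 role = c("control_best", "case_ccnc", "case_cancer")) {
  role <- match.arg(role)
  eligible <- switch(role,
    control_best = samples[samples$status == "control", ],
    case_ccnc = samples[samples$status == "case" & samples$histology != "cancer", ],
    case_cancer = samples[samples$status == "case" & samples$histology == "cancer", ])
  eligible <- eligible[eligible$core_id %in% rownames(pm$call), ]
  patients <- unique(samples$patient_id[samples$status ==
    (if (role == "control_best") "control" else "case")])
  picks <- lapply(patients, function(p) {
    ids <- eligible$core_id[eligible$patient_id == p]
    if (length(ids) == 0) return(NULL)
    tibble::tibble(patient_id = p, core_id = select_representative_core(pm, ids))
  })
  out <- dplyr::bind_rows(picks)
  dropped <- setdiff(patients, out$patient_id)
  if (role == "case_ccnc" && length(dropped) > 0) {
    message(length(dropped), " case(s) with no non-cancer core excluded from CCNC analysis")
  }
  attr(out, "dropped") <- dropped
  out
}

#' Read a sample sheet
#'
#' One row per biopsy core with patient linkage and histology. Required
#' columns: `patient_id`, `core_id`, `status` (`case`/`control`),
#' `histology` (`benign`/`abnormal`/`cancer`; abnormal = HGPIN or ASAP).
#' Optional: `age`, `core_age`, `psa`, `gleason`, `pct_involved`,
#' `followup_months`. Unknown columns are preserved.
#'
#' Validated invariants: unique core ids; a patient has a single status;
#' cancer histology only in case patients; `pct_involved` only on cancer
#' cores.
#'
#' @param path CSV path.
#' @return tibble, one row per core.
#' @export
read_sample_sheet <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param samples sample-sheet tibble to validate.
#' @export
validate_sample_sheet <- function(samples) {
  req <- c("patient_id", "core_id", "status", "histology")
  missing_cols <- setdiff(req, names(samples))
  if (length(missing_cols) > 0) {
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$core_id)) {
    stop("duplicate core_id in sample sheet")
  }
  if (!all(samples$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'")
  }
  if (!all(samples$histology %in% c("benign", "abnormal", "cancer"))) {
    stop("histology must be benign, abnormal or cancer")
  }
  st <- unique(samples[, c("patient_id", "status")])
  if (anyDuplicated(st$patient_id)) {
    stop("patient(s) with conflicting status: ",
         paste(unique(st$patient_id[duplicated(st$patient_id)]), collapse = ", "))
  }
  bad <- samples$histology == "cancer" & samples$status != "case"
  if (any(bad)) {
    stop("cancer cores in control patients: ",
         paste(samples$core_id[bad], collapse = ", "))
  }
  if ("pct_involved" %in% names(samples)) {
    bad <- !is.na(samples$pct_involved) & samples$histology != "cancer"
    if (any(bad)) {
      stop("pct_involved set on non-cancer core(s): ",
           paste(samples$core_id[bad], collapse = ", "))
    }
  }
  samples
}
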