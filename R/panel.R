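#' The 24-marker MS-qPCR panel definition
#'
#' Returns the default panel: 24 markers interrogated by 29 assays. Five
#' markers (RASSF5, MOXD1, KIFC2, NEUROG3, HEMK1) are covered by two assays
#' targeting different parts of the CpG island or opposing strands; their
#' calls are pooled downstream. All assays share a single Cq positivity
#' cutoff (default 35 cycles): amplification below the cutoff is scored as
#' methylated.
#'
#' @param cq_cutoff positivity cutoff in PCR cycles; a sample amplifying
#'   strictly below this cycle number is called methylated. Must be > 0.
#' @return A tibble with columns `assay_id`, `marker`, `cq_cutoff`.
#' @export
#' @examples
#' panel <- default_panel()
#' nrow(panel)                     # 29 assays
#' length(unique(panel$marker))    # 24 markers
default_panel <- function(cq_cutoff = 35) {
  stopifnot(is.numeric(cq_cutoff), length(cq_cutoff) == 1, cq_cutoff > 0)
  dual <- dual_assay_markers()
  single <- setdiff(panel_markers(), dual)
  panel <- tibble::tibble(
    assay_id = c(single, paste0(rep(dual, each = 2), c("_A", "_B"))),
    marker   = c(single, rep(dual, each = 2)),
    cq_cutoff = cq_cutoff
  )
  panel[order(match(panel$marker, panel_markers()), panel$assay_id), ]
}

#' Marker names of the default panel
#'
#' @return Character vector of the 24 marker names, in panel (report) order.
#' @export
panel_markers <- function() {
  c("CYBA", "HOXB5", "RASSF1", "SOCS3", "GRASP", "HAPLN3", "SLC16A5",
    "HOXD9", "ARHGEF10", "KLK10", "GSTP1", "RASSF5", "MOXD1", "RARB",
    "GPX7", "APC", "GFRA2", "LOXL2", "NEUROG3", "PTGS2", "ADCY4",
    "CXCL14", "HEMK1", "KIFC2")
}

#' @rdname panel_markers
#' @export
dual_assay_markers <- function() {
  c("RASSF5", "MOXD1", "KIFC2", "NEUROG3", "HEMK1")
}

#' Validate a panel definition
#'
#' Checks the structural invariants of a marker/assay map: unique assay ids,
#' each assay mapped to one marker, positive cutoffs.
#'
#' @param panel tibble as returned by [default_panel()] or [read_panel()].
#' @return The panel, invisibly, if valid; otherwise an error.
#' @export
validate_panel <- function(panel) {
  req <- c("assay_id", "marker", "cq_cutoff")
  if (!all(req %in% names(panel))) {
    stop("panel must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(panel$assay_id)) {
    stop("duplicate assay_id in panel: ",
         paste(unique(panel$assay_id[duplicated(panel$assay_id)]), collapse = ", "))
  }
  if (any(!is.finite(panel$cq_cutoff) | panel$cq_cutoff <= 0)) {
    stop("all cq_cutoff values must be finite and > 0")
  }
  invisible(panel)
}

#' Read / write a panel definition file
#'
#' The panel file is YAML (or JSON, which YAML subsumes) with one entry per
#' assay: `assay_id`, `marker`, and optionally `cq_cutoff` (defaulting to the
#' file-level `cq_cutoff`, then to 35).
#'
#' @param path file path.
#' @return `read_panel()`: a validated panel tibble. `write_panel()`: the
#'   path, invisibly.
#' @export
read_panel <- function(path) {
  doc <- yaml::read_yaml(path)
  default_cutoff <- doc$cq_cutoff %||% 35
  assays <- doc$assays
  if (is.null(assays)) stop("panel file must contain an 'assays' list")
  panel <- tibble::tibble(
    assay_id  = vapply(assays, function(a) as.character(a$assay_id), character(1)),
    marker    = vapply(assays, function(a) as.character(a$marker), character(1)),
    cq_cutoff = vapply(assays, function(a) as.numeric(a$cq_cutoff %||% default_cutoff),
                       numeric(1))
  )
  validate_panel(panel)
  panel
}

#' @rdname read_panel
#' @param panel panel tibble to write.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  doc <- list(
    cq_cutoff = panel$cq_cutoff[[1]],
    assays = lapply(seq_len(nrow(panel)), function(i) {
      list(assay_id = panel$assay_id[[i]], marker = panel$marker[[i]],
           cq_cutoff = panel$cq_cutoff[[i]])
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
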