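#' Tissue-class methylation profile
#'
#' A profile specifies, for one tissue class, the per-marker Bernoulli
#' probability of a positive methylation call, the log-normal law of the
#' semi-quantitative level given a positive call (on the `cutoff - Cq`
#' scale, in cycles), and the per-cell assay dropout rate.
#'
#' @param tissue_class one of `control_benign`, `control_abnormal`,
#'   `case_ccnc`, `case_abnormal`, `cancer`.
#' @param p_meth named numeric vector over the 24 markers, values in `[0,1]`.
#' @param level_meanlog,level_sdlog parameters of the log-normal level law.
#' @param dropout_rate probability that a (core, assay) cell is not run.
#' @return object of class `tissue_profile`.
#' @export
tissue_profile <- function(tissue_class, p_meth,
                           level_meanlog = 1.0, level_sdlog = 0.6,
                           dropout_rate = 0.007) {
  classes <- c("control_benign", "control_abnormal", "case_ccnc",
               "case_abnormal", "cancer")
  if (!tissue_class %in% classes) {
    stop("unknown tissue class: ", tissue_class)
  }
  stopifnot(all(p_meth >= 0 & p_meth <= 1),
            dropout_rate >= 0, dropout_rate < 1,
            level_sdlog > 0)
  structure(list(tissue_class = tissue_class,
                 p_meth = p_meth,
                 level_meanlog = level_meanlog,
                 level_sdlog = level_sdlog,
                 dropout_rate = dropout_rate),
            class = "tissue_profile")
}

#' Default tissue profiles calibrated to the published marker frequencies
#'
#' Builds the five tissue-class profiles from the panel's published
#' validation counts ([reference_panel_counts()]):
#'
#' * `cancer`: per-marker probability = observed cancer-core sensitivity
#'   (sum over markers approximately 13.8, matching the reported mean of
#'   13.66 methylated markers per cancer core).
#' * `control_benign` / `control_abnormal`: the published specificity column
#'   describes each control's *most methylated* core, so `1 - specificity`
#'   overstates the typical per-core frequency. The raw column (sum 1.92) is
#'   scaled to reproduce the reported per-core mean of 1.5 methylated
#'   markers over all control cores. The two control classes share a profile
#'   because abnormal (HGPIN/ASAP) and benign control cores showed no mean
#'   difference.
#' * `case_ccnc`: the CCNC sensitivity column (most-methylated non-cancer
#'   core per case; sum 6.52) scaled to the reported all-CCNC-core mean of
#'   5.9.
#' * `case_abnormal`: the CCNC column scaled to the reported abnormal-core
#'   mean of 4.36.
#'
#' With `calibrate = FALSE` the raw (selected-core) columns are used
#' unscaled, which reproduces selected-core analyses directly.
#'
#' Positive-call levels are log-normal with class-specific location (cancer
#' cores amplify earlier, i.e. larger `cutoff - Cq`); the level scale is a
#' modelling choice, not a published quantity.
#'
#' @param calibrate scale control/CCNC/abnormal probabilities to per-core
#'   means (default TRUE).
#' @param dropout_rate per-cell missingness rate (default 0.007,
#'   approximately the 36/5112 rate implied by the validation cohort).
#' @return named list of [tissue_profile()] objects.
#' @export
default_profiles <- function(calibrate = TRUE, dropout_rate = 0.007) {
  ref <- reference_panel_counts("marker")
  p_cancer <- setNames(ref$cancer_pos / ref$cancer_n, ref$label)
  p_control <- setNames(1 - ref$control_neg / ref$control_n, ref$label)
  p_ccnc <- setNames(ref$ccnc_pos / ref$ccnc_n, ref$label)
  if (calibrate) {
    p_control_b <- p_control * 1.5 / sum(p_control)
    p_ccnc_b <- p_ccnc * 5.9 / sum(p_ccnc)
    p_abn <- p_ccnc * 4.36 / sum(p_ccnc)
  } else {
    p_control_b <- p_control
    p_ccnc_b <- p_ccnc
    p_abn <- p_ccnc
  }
  list(
    control_benign = tissue_profile("control_benign", p_control_b,
                                    level_meanlog = 0.8, dropout_rate = dropout_rate),
    control_abnormal = tissue_profile("control_abnormal", p_control_b,
                                      level_meanlog = 0.8, dropout_rate = dropout_rate),
    case_ccnc = tissue_profile("case_ccnc", p_ccnc_b,
                               level_meanlog = 1.2, dropout_rate = dropout_rate),
    case_abnormal = tissue_profile("case_abnormal", p_abn,
                                   level_meanlog = 1.2, dropout_rate = dropout_rate),
    cancer = tissue_profile("cancer", p_cancer,
                            level_meanlog = 1.6, dropout_rate = dropout_rate)
  )
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults mirror the validation cohort: 67 controls (1-3 cores, mostly 2;
#' additional cores abnormal with the observed proportion) and 37 cases (one
#' cancer core plus 1, 2 or 4 non-cancer cores in the observed proportions).
#'
#' @param n_controls,n_cases patient counts.
#' @param profiles named list of tissue profiles ([default_profiles()]).
#' @param seed integer RNG seed; the generator is a pure function of the
#'   config.
#' @param rho exchangeable between-marker call correlation in `[0, 1)`;
#'   0 (default) draws markers independently (see [inject_correlation()]).
#' @param cq_cutoff cycle cutoff used to convert levels to Cq values.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 67, n_cases = 37,
                          profiles = default_profiles(), seed = 1L,
                          rho = 0, cq_cutoff = 35) {
  stopifnot(n_controls >= 1, n_cases >= 1, rho >= 0, rho < 1, cq_cutoff > 0)
  needed <- c("control_benign", "control_abnormal", "case_ccnc",
              "case_abnormal", "cancer")
  if (!all(needed %in% names(profiles))) {
    stop("profiles must cover tissue classes: ",
         paste(setdiff(needed, names(profiles)), collapse = ", "))
  }
  structure(list(n_controls = n_controls, n_cases = n_cases,
                 profiles = profiles, seed = as.integer(seed),
                 rho = rho, cq_cutoff = cq_cutoff),
            class = "cohort_config")
}

#' Draw per-marker binary calls for one tissue class
#'
#' Independent Bernoulli draws per marker at the profile's probabilities,
#' or exchangeable Gaussian-copula dependence when `rho > 0` (marginals
#' preserved either way).
#'
#' @param profile [tissue_profile()].
#' @param n number of cores to draw.
#' @param rho exchangeable correlation in `[0, 1)`.
#' @return integer matrix `n` x markers of 0/1 calls.
#' @export
sample_marker_calls <- function(profile, n, rho = 0) {
  p <- profile$p_meth
  if (rho == 0) {
    calls <- matrix(rbinom(n * length(p), 1L, rep(p, each = n)), nrow = n,
                    dimnames = list(NULL, names(p)))
  } else {
    calls <- inject_correlation(profile, rho)(n)
  }
  calls
}

#' Exchangeable-correlation call sampler (Gaussian copula)
#'
#' Returns a sampler drawing correlated binary calls with the profile's
#' marginal probabilities and an exchangeable latent correlation `rho`: the
#' latent variable for core i, marker m is
#' `Z_im = sqrt(rho) * W_i + sqrt(1 - rho) * E_im` with standard normal `W`,
#' `E`, and marker m is called when `Z_im < qnorm(p_m)`. `rho = 0` reduces
#' to independent sampling; as `rho -> 1` the per-core counts concentrate at
#' the extremes.
#'
#' @param profile [tissue_profile()].
#' @param rho exchangeable correlation, `0 <= rho < 1`.
#' @return function(n) returning an n x markers 0/1 matrix.
#' @export
inject_correlation <- function(profile, rho) {
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)")
  }
  p <- profile$p_meth
  thresh <- qnorm(p)
  function(n) {
    w <- rnorm(n)
    e <- matrix(rnorm(n * length(p)), nrow = n)
    z <- sqrt(rho) * w + sqrt(1 - rho) * e
    calls <- matrix(as.integer(t(t(z) < thresh)), nrow = n,
                    dimnames = list(NULL, names(p)))
    calls
  }
}

# Truncated log-normal on (0, upper): resample out-of-range draws.
rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  x <- rlnorm(n, meanlog, sdlog)
  bad <- which(x >= upper)
  while (length(bad) > 0) {
    x[bad] <- rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[x[bad] >= upper]
  }
  x
}

#' Generate a synthetic case/control cohort
#'
#' Draws patients, cores, per-marker methylation calls and Cq values from a
#' [cohort_config()]. For each core, marker calls are Bernoulli draws from
#' its tissue-class profile; a positive marker receives a level drawn from
#' the class's log-normal law and a Cq of `cutoff - level`. For dual-assay
#' markers, the first assay carries the marker's level; the second assay
#' independently amplifies with probability 0.7 at a level no larger than
#' the first (so OR/max pooling recovers the marker call and level exactly).
#' Negative markers yield no amplification on all their assays. Dropout is
#' applied last, marking cells not-run.
#'
#' Output is structurally identical to parsed real input: a sample sheet and
#' a wide Cq table consumable by [build_panel_matrix()].
#'
#' @param config [cohort_config()].
#' @param panel panel definition; its marker set must match the profiles.
#' @return list with elements `samples` (sample-sheet tibble) and `cq`
#'   (wide Cq tibble; `NA` = no amplification, `NaN` = not run). Reproducible:
#'   a fixed config (including seed) gives identical output.
#' @export
generate_cohort <- function(config = cohort_config(), panel = default_panel()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_panel(panel)
  withr::with_seed(config$seed, {
    samples <- draw_cohort_structure(config)
    cq <- draw_cq_values(samples, config, panel)
    list(samples = samples, cq = cq)
  })
}

# Patient/core skeleton matching the validation cohort's structure:
# controls mostly contribute 2 cores (first benign, extras abnormal with the
# observed proportion); cases contribute one cancer core plus 1, 2 or 4
# non-cancer cores.
draw_cohort_structure <- function(config) {
  rows <- list()
  for (i in seq_len(config$n_controls)) {
    pid <- sprintf("CTRL%03d", i)
    n_cores <- sample(c(1L, 2L, 3L), 1, prob = c(10, 56, 1))
    hist <- c("benign",
              ifelse(runif(max(0, n_cores - 1)) < 20 / 58, "abnormal", "benign"))
    rows[[length(rows) + 1]] <- tibble::tibble(
      patient_id = pid,
      core_id = sprintf("%s_c%d", pid, seq_len(n_cores)),
      status = "control", histology = hist[seq_len(n_cores)],
      age = round(pmin(86, pmax(49, rnorm(1, 63.7, 8.1))), 1),
      core_age = round(runif(n_cores, 0.5, 6), 1),
      psa = round(pmax(0.1, rnorm(1, 7.3, 4.6)), 1),
      gleason = NA_integer_, pct_involved = NA_real_,
      followup_months = round(runif(1, 19, 64))
    )
  }
  for (i in seq_len(config$n_cases)) {
    pid <- sprintf("CASE%03d", i)
    n_noncancer <- sample(c(1L, 2L, 4L), 1, prob = c(28, 4, 5))
    hist <- c("cancer",
              ifelse(runif(n_noncancer) < 13 / 49, "abnormal", "benign"))
    n_cores <- n_noncancer + 1L
    gl <- sample(4:9, 1, prob = c(1, 4, 14, 12, 5, 2))
    rows[[length(rows) + 1]] <- tibble::tibble(
      patient_id = pid,
      core_id = sprintf("%s_c%d", pid, seq_len(n_cores)),
      status = "case", histology = hist,
      age = round(pmin(86, pmax(49, rnorm(1, 70.9, 9.0))), 1),
      core_age = round(runif(n_cores, 0.5, 6), 1),
      psa = round(pmax(0.1, rnorm(1, 6.5, 2.3)), 1),
      gleason = ifelse(hist == "cancer", gl, NA_integer_),
      pct_involved = ifelse(hist == "cancer",
                            round(pmin(80, pmax(1, rlnorm(n_cores, 3, 0.8)))),
                            NA_real_),
      followup_months = NA_real_
    )
  }
  dplyr::bind_rows(rows)
}

core_tissue_class <- function(status, histology) {
  dplyr::case_when(
    histology == "cancer" ~ "cancer",
    status == "case" & histology == "abnormal" ~ "case_abnormal",
    status == "case" ~ "case_ccnc",
    histology == "abnormal" ~ "control_abnormal",
    TRUE ~ "control_benign"
  )
}

draw_cq_values <- function(samples, config, panel) {
  classes <- core_tissue_class(samples$status, samples$histology)
  markers <- unique(panel$marker)
  n <- nrow(samples)
  cutoff <- config$cq_cutoff
  lvl <- matrix(0, n, length(markers), dimnames = list(samples$core_id, markers))
  for (cls in unique(classes)) {
    profile <- config$profiles[[cls]]
    if (is.null(profile)) stop("no profile for tissue class: ", cls)
    idx <- which(classes == cls)
    calls <- sample_marker_calls(profile, length(idx), rho = config$rho)
    calls <- calls[, markers, drop = FALSE]
    pos <- which(calls == 1L)
    levels <- matrix(0, length(idx), length(markers))
    if (length(pos) > 0) {
      levels[pos] <- rlnorm_trunc(length(pos), profile$level_meanlog,
                                  profile$level_sdlog, upper = cutoff - 0.5)
    }
    lvl[idx, ] <- levels
  }
  # marker levels -> per-assay Cq values
  cq <- tibble::tibble(core_id = samples$core_id)
  dropout <- vapply(classes, function(cls) config$profiles[[cls]]$dropout_rate,
                    numeric(1))
  for (j in seq_len(nrow(panel))) {
    a <- panel$assay_id[j]
    mk <- panel$marker[j]
    second <- grepl("_B$", a) && mk %in% dual_assay_markers()
    marker_level <- lvl[, mk]
    if (second) {
      amplifies <- marker_level > 0 & runif(n) < 0.7
      assay_level <- marker_level * runif(n, 0.3, 1)
      assay_level[!amplifies] <- 0
    } else {
      assay_level <- marker_level
    }
    vals <- ifelse(assay_level > 0, cutoff - assay_level, NA_real_)
    vals[runif(n) < dropout] <- NaN
    cq[[a]] <- vals
  }
  cq
}
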