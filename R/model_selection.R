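#' Stratified train/test split of a patient-level cohort
#'
#' Randomly partitions patients into a training set (two thirds, floored
#' within each status stratum) and a test set (the remainder), stratified by
#' case/control status. At the validation cohort's sizes (67 controls, 37
#' cases) this yields 44 + 23 controls and 24 + 13 cases. Deterministic
#' given the seed.
#'
#' @param status character/factor vector of `"case"`/`"control"` per
#'   patient-level unit (one representative core per patient).
#' @param train_frac training fraction per stratum (default 2/3, floored).
#' @param seed integer RNG seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(status, train_frac = 2 / 3, seed = 1L) {
  stopifnot(all(status %in% c("case", "control")))
  withr::with_seed(as.integer(seed), {
    train <- integer(0)
    for (s in c("control", "case")) {
      idx <- which(status == s)
      n_train <- floor(train_frac * length(idx))
      if (n_train < 1 || n_train >= length(idx)) {
        stop("stratum '", s, "' too small to split")
      }
      train <- c(train, sort(sample(idx, n_train)))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(status), train))
  })
}

# Ridge-penalised logistic regression by Newton-Raphson (IRLS).
# A small quadratic penalty on the non-intercept coefficients keeps the fit
# finite under complete separation, which is common when a handful of nearly
# perfect binary markers are fitted on ~70 patients; the penalty is weak
# enough to leave the ranking of risk scores essentially untouched.
ridge_logistic <- function(x, y, lambda = 0.1, max_iter = 30, tol = 1e-6) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  beta <- rep(0, ncol(x))
  pen <- c(0, rep(lambda, ncol(x) - 1))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    grad <- drop(crossprod(x, y - p)) - pen * beta
    hess <- crossprod(x * w, x) + diag(pen, ncol(x))
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(coefficients = setNames(beta, colnames(x)), converged = converged)
}

logistic_scores <- function(coefficients, x) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  covs <- names(coefficients)
  missing_cov <- setdiff(covs, colnames(x))
  if (length(missing_cov) > 0) {
    stop("covariate(s) absent from data: ", paste(missing_cov, collapse = ", "))
  }
  drop(x[, covs, drop = FALSE] %*% coefficients)
}

#' Covariate matrix for marker-based logistic models
#'
#' Builds the per-patient design matrix from a panel matrix: one column per
#' marker, either the binary methylation indicator (`mode = "indicator"`) or
#' the semi-quantitative level (`mode = "level"`). Missing cells (assay not
#' run) are treated as not detected (0), the convention used for risk
#' scoring. Optionally appends an `age` column.
#'
#' @param pm panel_matrix.
#' @param cores core ids, one representative core per patient, in patient
#'   order.
#' @param mode `"indicator"` or `"level"`.
#' @param age optional numeric vector of patient ages aligned with `cores`.
#' @return numeric matrix, rows named by core id.
#' @export
model_covariates <- function(pm, cores, mode = c("indicator", "level"),
                             age = NULL) {
  mode <- match.arg(mode)
  sub <- pm_subset(pm, cores = cores)
  x <- if (mode == "indicator") sub$call else sub$level
  x[is.na(x)] <- 0
  x <- matrix(as.numeric(x), nrow = nrow(x), dimnames = dimnames(x))
  if (!is.null(age)) {
    stopifnot(length(age) == nrow(x))
    x <- cbind(x, age = age)
  }
  x
}

# Stratified fold assignment: within each class, shuffle and deal round-robin.
make_folds <- function(y, nfolds, seed) {
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    fold
  })
}

# Mean per-fold held-out AUC for one covariate subset.
cv_auc_subset <- function(x, y, folds, lambda) {
  aucs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- ridge_logistic(x[tr, , drop = FALSE], y[tr], lambda)
    sc <- logistic_scores(fit$coefficients, x[!tr, , drop = FALSE])
    yv <- y[!tr]
    roc_curve(sc[yv == 1], sc[yv == 0], "risk_score")$auc
  }, numeric(1))
  mean(aucs)
}

#' Exhaustive best-subsets logistic model ranking
#'
#' Enumerates every 1- to `max_size`-marker combination (2,324 subsets at
#' the default 24 markers and size 3; each subset additionally paired with
#' age when `include_age = TRUE`), fits a weakly ridge-penalised logistic
#' regression, and ranks subsets by stratified 4-fold cross-validated AUC on
#' the training data. Final coefficients are refit on the full training set;
#' the test data plays no role here ([evaluate_frozen()] scores it with the
#' frozen coefficients).
#'
#' Ranking ties are broken by smaller subset, then lexicographic covariate
#' names; reruns with the same seed reproduce the ranking exactly.
#'
#' @param x training covariate matrix ([model_covariates()]); columns are
#'   candidate covariates (an `age` column, if present, is handled per
#'   `include_age` and never enters marker enumeration).
#' @param y binary outcome vector (1 = case) aligned with `x`'s rows.
#' @param max_size largest marker subset (default 3).
#' @param mode covariate mode label recorded in the output.
#' @param include_age also fit each subset with age appended (requires an
#'   `age` column in `x`).
#' @param nfolds cross-validation folds (default 4; each stratum needs >= 2
#'   units per fold).
#' @param lambda ridge penalty on non-intercept coefficients (default 0.1).
#' @param seed integer seed for fold assignment.
#' @return tibble of class `model_ranking`, one row per candidate, ranked:
#'   `rank`, `covariates`, `size`, `mode`, `cv_auc`, `converged`,
#'   `coefficients` (list column of named vectors).
#' @export
best_subsets <- function(x, y, max_size = 3, mode = "indicator",
                         include_age = FALSE, nfolds = 4, lambda = 0.1,
                         seed = 1L) {
  stopifnot(is.matrix(x), length(y) == nrow(x), all(y %in% 0:1))
  markers <- setdiff(colnames(x), "age")
  if (include_age && !"age" %in% colnames(x)) {
    stop("include_age = TRUE requires an 'age' column in x")
  }
  min_per_fold <- min(table(y)) / nfolds
  if (min_per_fold < 2) {
    stop("need at least ", 2 * nfolds, " units in the smaller stratum for ",
         nfolds, "-fold cross-validation")
  }
  folds <- make_folds(y, nfolds, seed)
  subsets <- unlist(lapply(seq_len(max_size), function(sz)
    combn(markers, sz, simplify = FALSE)), recursive = FALSE)
  if (include_age) {
    subsets <- c(subsets, lapply(subsets, function(s) c(s, "age")))
  }
  rows <- lapply(subsets, function(covs) {
    xs <- x[, covs, drop = FALSE]
    cv <- cv_auc_subset(xs, y, folds, lambda)
    fit <- ridge_logistic(xs, y, lambda)
    tibble::tibble(covariates = paste(covs, collapse = " + "),
                   size = length(setdiff(covs, "age")),
                   mode = mode, cv_auc = cv, converged = fit$converged,
                   coefficients = list(fit$coefficients))
  })
  out <- dplyr::bind_rows(rows)
  ord <- order(-out$cv_auc, out$size, out$covariates)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", setdiff(names(out), "rank"))]
  class(out) <- c("model_ranking", class(out))
  out
}

#' Top-ranked models per subset size
#'
#' @param ranking tibble from [best_subsets()].
#' @param n_per_size how many models to keep per subset size (default 5).
#' @return tibble in report shape.
#' @export
top_models <- function(ranking, n_per_size = 5) {
  ranking |>
    dplyr::group_by(.data$size) |>
    dplyr::slice_min(.data$rank, n = n_per_size) |>
    dplyr::ungroup()
}

#' Frozen-coefficient out-of-sample AUC
#'
#' Applies a trained candidate's coefficients, without re-estimation, to
#' held-out test data and computes the AUC of the resulting risk scores -
#' an honest estimate of out-of-sample discrimination.
#'
#' @param coefficients named coefficient vector (intercept + covariates), as
#'   stored in the `coefficients` list-column of [best_subsets()] output.
#' @param x_test test covariate matrix containing all model covariates.
#' @param y_test binary outcome for the test units.
#' @return the test AUC (scalar).
#' @export
evaluate_frozen <- function(coefficients, x_test, y_test) {
  stopifnot(length(y_test) == nrow(x_test), all(y_test %in% 0:1))
  sc <- logistic_scores(coefficients, x_test)
  roc_curve(sc[y_test == 1], sc[y_test == 0], "risk_score")$auc
}
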