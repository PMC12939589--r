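#' Fit an elastic-net-penalized Cox model at a fixed penalty
#'
#' Minimizes the negative log partial likelihood (Breslow tie handling) plus
#' `lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)`. Zero-variance
#' features are dropped before fitting and reported with coefficient 0.
#'
#' @param x Numeric feature matrix (patients x features, named columns).
#' @param time Survival times (> 0).
#' @param event Event indicator (1 = event, 0 = censored); at least 2 events
#'   are required.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (0 = ridge,
#'   1 = lasso).
#' @param lambda Penalty strength, >= 0.
#' @param standardize Standardize features to unit variance within this fit
#'   (default `TRUE`); coefficients are returned on the original scale as
#'   glmnet reports them.
#' @param thresh Coordinate-descent convergence threshold.
#' @return An object of class `cox_fit`: coefficients (one per input
#'   feature), `alpha`, `lambda`, `converged`, `n_iterations`, and the names
#'   of any dropped constant features.
#' @export
fit_penalized_cox <- function(x, time, event, alpha, lambda,
                              standardize = TRUE, thresh = 1e-10) {
  x <- as.matrix(x)
  if (sum(event) < 2) stop("need at least 2 events to fit a Cox model")
  stopifnot(alpha >= 0, alpha <= 1, lambda >= 0)
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " zero-variance feature(s): ", paste(dropped, collapse = ", "))
  }
  keep <- sds > 0
  beta <- stats::setNames(rep(0, ncol(x)), colnames(x))
  y <- survival::Surv(time, event)
  # warm-started descent along a short path ending at the requested lambda
  lam_path <- unique(sort(lambda * c(16, 8, 4, 2, 1), decreasing = TRUE))
  if (lambda == 0) lam_path <- c(1, 0.25, 0.05, 0.01, 0)
  xk <- x[, keep, drop = FALSE]
  pad <- ncol(xk) < 2  # glmnet requires >= 2 columns
  if (pad) xk <- cbind(xk, .pad. = 0)
  fit <- glmnet::glmnet(xk, y, family = "cox",
                        alpha = alpha, lambda = lam_path,
                        standardize = standardize, thresh = thresh,
                        maxit = 1e7)
  b <- as.numeric(fit$beta[, ncol(fit$beta)])
  if (pad) b <- b[-length(b)]
  beta[colnames(x)[keep]] <- b
  structure(list(coefficients = beta, alpha = alpha, lambda = lambda,
                 converged = fit$jerr == 0, n_iterations = fit$npasses,
                 dropped = dropped),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  nz <- sum(abs(x$coefficients) > 0)
  cat(sprintf(
    "Penalized Cox fit: alpha = %.2f, lambda = %.4g, %d/%d non-zero\n",
    x$alpha, x$lambda, nz, length(x$coefficients)))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

# Event-stratified fold assignment: shuffle fold labels separately within
# events and censorings so every fold keeps events.
stratified_foldid <- function(event, cv_folds) {
  foldid <- integer(length(event))
  for (e in unique(event)) {
    idx <- which(event == e)
    foldid[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  foldid
}

#' Select the Cox penalty by cross-validated partial-likelihood deviance
#'
#' Builds an internally generated geometric lambda path, evaluates the
#' cross-validated partial-likelihood deviance with event-stratified folds,
#' and returns the lambda minimizing the mean out-of-fold deviance. When two
#' lambdas tie, the larger (more parsimonious) one is kept, which is how the
#' first index along a decreasing path resolves.
#'
#' @inheritParams fit_penalized_cox
#' @param cv_folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param nlambda Path length (default 100).
#' @return The selected lambda, with the underlying `cv.glmnet` object
#'   attached as attribute `"cvfit"`.
#' @export
cv_select_lambda <- function(x, time, event, alpha, cv_folds = 10, seed = 1,
                             nlambda = 100, standardize = TRUE,
                             thresh = 1e-7) {
  x <- as.matrix(x)
  stopifnot(cv_folds >= 2, cv_folds <= nrow(x))
  if (sum(event) < cv_folds) {
    stop("too few events (", sum(event), ") for ", cv_folds,
         " event-stratified folds")
  }
  set.seed(seed)
  foldid <- stratified_foldid(event, cv_folds)
  y <- survival::Surv(time, event)
  cvfit <- glmnet::cv.glmnet(x, y, family = "cox", alpha = alpha,
                             foldid = foldid, nlambda = nlambda,
                             standardize = standardize, thresh = thresh)
  lam <- cvfit$lambda.min
  attr(lam, "cvfit") <- cvfit
  lam
}

#' Rank features by elastic-net selection frequency
#'
#' The central fitting routine: over `n_runs` Monte Carlo subsamples (a
#' fraction of patients drawn without replacement) and every mixing value in
#' `alpha_grid`, a penalized Cox model is fitted at the penalty chosen by
#' `cv_folds`-fold cross-validated partial-likelihood deviance, and each
#' feature with a coefficient of magnitude above `nonzero_tol` is counted as
#' selected. Selection counts over all `n_runs * length(alpha_grid)` models
#' give a stability-style importance ranking: features that survive
#' shrinkage across many resamples and regularization settings rank highest.
#' At `alpha = 0` (pure ridge) no coefficient is exactly zero, so every
#' retained feature counts as selected in those models.
#'
#' Failed model fits (e.g. cross-validation collapsing on a degenerate
#' subsample) do not silently deflate counts: each failure is recorded as
#' lost exposure, so for every feature
#' `count + failures + not_selected == total_models`.
#'
#' @param cohort A [new_cohort()] object; only the radiomic features enter
#'   the penalized model (clinical covariates are reserved for downstream
#'   stratification).
#' @param n_runs Monte Carlo repetitions (default 100).
#' @param alpha_grid Mixing values (default `seq(0, 1, 0.1)`, 11 values).
#' @param cv_folds Folds for lambda selection (default 10).
#' @param subsample_fraction Fraction of patients drawn per run, without
#'   replacement (default 0.8).
#' @param nonzero_tol Coefficient magnitude below which a feature counts as
#'   unselected (default 1e-8).
#' @param nlambda Lambda path resolution passed to the CV search.
#' @param seed Integer seed; per-run seeds are derived deterministically.
#' @return An object of class `freq_ranking` with per-feature `counts`,
#'   `failures`, `total_models`, competition `ranks`, the feature
#'   `categories`, and the configuration used.
#' @export
rank_biomarkers <- function(cohort, n_runs = 100, alpha_grid = seq(0, 1, 0.1),
                            cv_folds = 10, subsample_fraction = 0.8,
                            nonzero_tol = 1e-8, nlambda = 100, seed = 1) {
  validate_cohort(cohort)
  stopifnot(n_runs >= 1, length(alpha_grid) >= 1,
            !anyDuplicated(alpha_grid),
            all(alpha_grid >= 0), all(alpha_grid <= 1),
            cv_folds >= 2, cv_folds <= n_patients(cohort),
            subsample_fraction > 0, subsample_fraction <= 1)
  x <- cohort$features
  p <- ncol(x)
  n <- nrow(x)
  counts <- failures <- stats::setNames(integer(p), colnames(x))
  total <- n_runs * length(alpha_grid)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  m <- max(2L, floor(subsample_fraction * n))
  for (run in seq_len(n_runs)) {
    set.seed(run_seeds[run])
    idx <- sample.int(n, m)
    foldid <- stratified_foldid(cohort$event[idx], cv_folds)
    xs <- x[idx, , drop = FALSE]
    y <- survival::Surv(cohort$time[idx], cohort$event[idx])
    for (a in alpha_grid) {
      sel <- tryCatch({
        # selection depends on the sparsity pattern, not coefficient
        # precision, so a moderate threshold suffices here
        cvfit <- glmnet::cv.glmnet(xs, y, family = "cox", alpha = a,
                                   foldid = foldid, nlambda = nlambda,
                                   standardize = TRUE, thresh = 1e-5)
        b <- as.numeric(glmnet::coef.glmnet(cvfit, s = "lambda.min"))
        abs(b) > nonzero_tol
      }, error = function(e) {
        warning("fit failed (run ", run, ", alpha ", a, "): ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(sel)) failures <- failures + 1L else counts <- counts + sel
    }
  }
  structure(list(
    counts = counts,
    failures = failures,
    total_models = total,
    ranks = competition_rank(counts),
    categories = cohort$categories,
    config = list(n_runs = n_runs, alpha_grid = alpha_grid,
                  cv_folds = cv_folds,
                  subsample_fraction = subsample_fraction,
                  nonzero_tol = nonzero_tol, nlambda = nlambda, seed = seed)
  ), class = "freq_ranking")
}

# Competition ("1224") ranking by descending count: tied counts share the
# better rank.
competition_rank <- function(counts) {
  r <- vapply(counts, function(ci) sum(counts > ci) + 1L, integer(1))
  stats::setNames(r, names(counts))
}

#' Extract the top of a frequency ranking
#'
#' Orders features by descending selection count with tie-aware competition
#' ranks (equal counts share the better rank); ties are broken by feature
#' name for display only, and tie-group membership is preserved via the
#' `rank` column.
#'
#' @param freq A `freq_ranking`.
#' @param top_k How many features to return (default all); a value larger
#'   than the feature count returns the full list.
#' @return A data frame with columns `rank`, `feature`, `category`, `count`,
#'   `total_models`.
#' @export
rank_features <- function(freq, top_k = Inf) {
  stopifnot(inherits(freq, "freq_ranking"), top_k >= 1)
  ord <- order(-freq$counts, names(freq$counts))
  k <- min(top_k, length(freq$counts))
  sel <- ord[seq_len(k)]
  data.frame(rank = unname(freq$ranks[sel]),
             feature = names(freq$counts)[sel],
             category = unname(freq$categories[names(freq$counts)[sel]]),
             count = unname(freq$counts[sel]),
             total_models = freq$total_models,
             stringsAsFactors = FALSE)
}

#' Top tie group of a frequency ranking
#'
#' Features sharing the maximal selection count (the rank-1 tie group), the
#' natural candidate set for redundancy analysis.
#'
#' @param freq A `freq_ranking`.
#' @return Character vector of feature names, sorted.
#' @export
top_tie_group <- function(freq) {
  stopifnot(inherits(freq, "freq_ranking"))
  sort(names(freq$counts)[freq$counts == max(freq$counts)])
}

#' @export
print.freq_ranking <- function(x, n = 10, ...) {
  cat("Elastic-net selection-frequency ranking\n")
  cat("  ", x$config$n_runs, "runs x", length(x$config$alpha_grid),
      "alpha values =", x$total_models, "models;",
      x$config$cv_folds, "-fold CV lambda\n")
  if (any(x$failures > 0)) {
    cat("  failed fits (lost exposure): up to", max(x$failures),
        "per feature\n")
  }
  print(utils::head(rank_features(x), n), row.names = FALSE)
  invisible(x)
}

#' @export
summary.freq_ranking <- function(object, top_k = 16, ...) {
  out <- list(table = rank_features(object, top_k),
              tie_group = top_tie_group(object),
              total_models = object$total_models,
              n_failures = sum(object$failures))
  class(out) <- "summary.freq_ranking"
  out
}

#' @export
print.summary.freq_ranking <- function(x, ...) {
  cat("Top-ranked biomarkers (", x$total_models, " models evaluated):\n",
      sep = "")
  print(x$table, row.names = FALSE)
  cat("Rank-1 tie group:", paste(x$tie_group, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.freq_ranking <- function(x, top_k = 16, ...) {
  tab <- rank_features(x, top_k)
  op <- graphics::par(mar = c(5, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(tab$count), names.arg = rev(tab$feature),
                    horiz = TRUE, las = 1,
                    xlab = sprintf("selection count (of %d models)",
                                   x$total_models),
                    main = "Selection-frequency ranking", ...)
  invisible(x)
}

#' @export
as.data.frame.freq_ranking <- function(x, ...) rank_features(x)

#' Write a frequency table to CSV
#'
#' Columns `rank`, `feature`, `category`, `count`, `total_models`.
#'
#' @param freq A `freq_ranking`.
#' @param path Output CSV path.
#' @param top_k Rows to write (default all).
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freq, path, top_k = Inf) {
  utils::write.csv(rank_features(freq, top_k), path, row.names = FALSE)
  invisible(path)
}
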