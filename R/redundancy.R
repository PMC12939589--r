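#' Spearman correlation matrix of selected features
#'
#' Rank correlation (average ranks for ties) among a set of cohort features.
#' A zero-variance feature has no defined rank correlation; its entries are
#' returned as `NA` with a warning.
#'
#' @param cohort A [new_cohort()] object with at least 3 patients.
#' @param features Character vector of at least 2 feature names.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(cohort, features) {
  validate_cohort(cohort)
  stopifnot(length(features) >= 2, n_patients(cohort) >= 3)
  missing_f <- setdiff(features, colnames(cohort$features))
  if (length(missing_f)) {
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  }
  x <- cohort$features[, features, drop = FALSE]
  degenerate <- apply(x, 2, function(v) stats::sd(v) == 0)
  if (any(degenerate)) {
    warning("zero-variance feature(s), correlation undefined: ",
            paste(features[degenerate], collapse = ", "))
  }
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Representativeness strength score (RSS)
#'
#' For a feature within a candidate set, the mean absolute Spearman
#' correlation with the remaining set members. A high RSS marks the feature
#' that best captures the information shared across the set.
#'
#' @param rho A Spearman correlation matrix over the candidate set (as from
#'   [spearman_matrix()]).
#' @param feature A feature name present in `rho`; the set must have at
#'   least 2 members.
#' @return RSS in `[0, 1]`.
#' @export
compute_rss <- function(rho, feature) {
  stopifnot(is.matrix(rho), nrow(rho) == ncol(rho))
  if (nrow(rho) < 2) stop("RSS needs a candidate set of at least 2 features")
  if (!feature %in% rownames(rho)) stop("feature not in set: ", feature)
  mean(abs(rho[feature, setdiff(rownames(rho), feature)]))
}

#' Select the representative biomarker among top-ranked features
#'
#' Takes the rank-1 tie group of a frequency ranking (or, if no tie exists,
#' the `top_k` features by count), computes the pairwise Spearman matrix and
#' each candidate's representativeness strength score, and returns the
#' candidate with maximal RSS. Ties in RSS are broken by higher selection
#' frequency, then by feature name. If the maximal RSS falls below
#' `threshold` the candidates are mutually weakly correlated and a
#' low-redundancy warning is raised (the threshold is a descriptive flag,
#' not a filter).
#'
#' @param freq A `freq_ranking`.
#' @param cohort The cohort the ranking was fitted on.
#' @param top_k Fallback candidate-set size when the top count is untied
#'   (default 5).
#' @param threshold Absolute-correlation level regarded as redundant
#'   (default 0.6).
#' @return An object of class `correlation_report`: candidate `features`,
#'   Spearman matrix `rho`, per-feature `rss`, the chosen `representative`,
#'   the `threshold`, and candidate selection `counts`.
#' @export
select_representative <- function(freq, cohort, top_k = 5, threshold = 0.6) {
  stopifnot(inherits(freq, "freq_ranking"))
  validate_cohort(cohort)
  tie <- top_tie_group(freq)
  candidates <- if (length(tie) >= 2) tie else rank_features(freq, top_k)$feature
  if (length(candidates) < 2) stop("candidate set must have >= 2 features")
  rho <- spearman_matrix(cohort, candidates)
  rss <- vapply(candidates, function(f) compute_rss(rho, f), numeric(1))
  cnt <- freq$counts[candidates]
  ord <- order(-rss, -cnt, candidates)
  rep_feature <- candidates[ord[1]]
  if (max(rss, na.rm = TRUE) < threshold) {
    warning(sprintf(
      "low redundancy: maximal RSS %.3f is below the %.2f flag; candidates are weakly correlated",
      max(rss, na.rm = TRUE), threshold))
  }
  structure(list(features = candidates, rho = rho, rss = rss,
                 representative = rep_feature, threshold = threshold,
                 counts = cnt),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, digits = 3, ...) {
  cat("Redundancy analysis of", length(x$features), "candidate features\n")
  cat("  |rho| >=", x$threshold, "flags redundancy\n")
  df <- data.frame(feature = x$features, count = unname(x$counts),
                   rss = round(unname(x$rss), digits))
  df <- df[order(-df$rss), ]
  print(df, row.names = FALSE)
  cat("Representative:", x$representative,
      sprintf("(RSS = %.*f)\n", digits, x$rss[[x$representative]]))
  invisible(x)
}

#' Write a correlation report to CSV
#'
#' Writes the Spearman matrix to `matrix_path` and, optionally, a one-line
#' representative record (`feature,rss,threshold`) to `representative_path`.
#'
#' @param report A `correlation_report`.
#' @param matrix_path CSV path for the correlation matrix.
#' @param representative_path Optional CSV path for the representative
#'   record.
#' @return `matrix_path`, invisibly.
#' @export
write_correlation_report <- function(report, matrix_path,
                                     representative_path = NULL) {
  utils::write.csv(data.frame(feature = rownames(report$rho), report$rho,
                              check.names = FALSE),
                   matrix_path, row.names = FALSE)
  if (!is.null(representative_path)) {
    utils::write.csv(data.frame(feature = report$representative,
                                rss = report$rss[[report$representative]],
                                threshold = report$threshold),
                     representative_path, row.names = FALSE)
  }
  invisible(matrix_path)
}
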