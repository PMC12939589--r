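#' Binary patient factors
#'
#' A `binary_factor` labels every patient in a cohort with one of two group
#' names and records the rule that produced the split (the median threshold
#' for continuous variables, or the categorical partition).
#'
#' @param name Factor name (e.g. `"stage"`, `"age"`, `"biomarker:Busyness"`).
#' @param labels Character vector of per-patient labels.
#' @param levels Length-2 character vector, low group first.
#' @param threshold The numeric cut used, or `NA` for categorical splits.
#' @return An object of class `binary_factor`.
#' @export
binary_factor <- function(name, labels, levels, threshold = NA_real_) {
  stopifnot(length(levels) == 2, all(labels %in% levels), !anyNA(labels))
  structure(list(name = name,
                 labels = factor(labels, levels = levels),
                 levels = levels, threshold = threshold),
            class = "binary_factor")
}

#' @export
print.binary_factor <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Binary factor '%s': %s = %d, %s = %d", x$name,
              x$levels[1], tab[[1]], x$levels[2], tab[[2]]))
  if (!is.na(x$threshold)) cat(sprintf(" (threshold %.4g)", x$threshold))
  cat("\n")
  invisible(x)
}

#' Median dichotomization
#'
#' Splits a continuous variable at its sample median: values at or below the
#' median take the low label, values above it the high label. With an even
#' number of distinct values this yields two equal halves; ties at the cut
#' all fall in the low group (a deterministic convention).
#'
#' @param values Numeric vector, length >= 2, not all identical.
#' @param labels Length-2 character vector `(low, high)`
#'   (default `c("Low", "High")`).
#' @param name Factor name recorded on the result.
#' @return A [binary_factor()] with the median stored as `threshold`.
#' @export
binarize_by_median <- function(values, labels = c("Low", "High"),
                               name = "median-split") {
  stopifnot(length(values) >= 2, !anyNA(values))
  if (length(unique(values)) == 1) {
    stop("all values identical; no median split possible")
  }
  med <- stats::median(values)
  binary_factor(name, ifelse(values <= med, labels[1], labels[2]),
                labels, threshold = med)
}

#' Low/high stage dichotomization
#'
#' Combines stages I and II into the Low-Stage class and IIIa/IIIb into the
#' High-Stage class.
#'
#' @param stages Character or factor of stage tokens (`I`, `II`, `IIIa`,
#'   `IIIb`; case-insensitive).
#' @return A [binary_factor()] named `"stage"`.
#' @export
binarize_stage <- function(stages) {
  s <- canonicalize_stage(stages)
  binary_factor("stage", ifelse(s %in% c("I", "II"), "Low", "High"),
                c("Low", "High"))
}

#' Young/old age dichotomization
#'
#' Median split of age: at or below the median is Young, above it Old.
#'
#' @param ages Numeric ages.
#' @return A [binary_factor()] named `"age"` with labels Young/Old.
#' @export
binarize_age <- function(ages) {
  bf <- binarize_by_median(ages, labels = c("Young", "Old"), name = "age")
  bf
}

#' Gender as a binary factor
#'
#' @param gender Character or factor with female/male tokens
#'   (case-insensitive).
#' @return A [binary_factor()] named `"gender"` with labels Female/Male.
#' @export
binarize_gender <- function(gender) {
  g <- tolower(as.character(gender))
  stopifnot(all(g %in% c("female", "male")))
  binary_factor("gender", ifelse(g == "female", "Female", "Male"),
                c("Female", "Male"))
}

#' Biomarker dichotomization on a cohort
#'
#' Median split of one radiomic feature, labelled Low/High.
#'
#' @param cohort A [new_cohort()] object.
#' @param feature Feature name.
#' @return A [binary_factor()] named `"biomarker:<feature>"`.
#' @export
binarize_biomarker <- function(cohort, feature) {
  validate_cohort(cohort)
  if (!feature %in% colnames(cohort$features)) {
    stop("unknown feature: ", feature)
  }
  binarize_by_median(cohort$features[, feature],
                     name = paste0("biomarker:", feature))
}

#' Build nested strata from binary factors
#'
#' Crosses a list of binary factors into the full grid of label combinations
#' ("cells"), recording each cell's member indices and count. The cells
#' partition the cohort: disjoint, exhaustive, counts summing to n.
#'
#' @param cohort A [new_cohort()] object.
#' @param factors List of [binary_factor()] objects labelled on this cohort.
#' @return An object of class `stratum_set` with the factor names, a
#'   per-patient assignment data frame, the list of `cells`
#'   (label tuple -> integer indices), and a long-format `counts` data
#'   frame.
#' @export
build_strata <- function(cohort, factors) {
  validate_cohort(cohort)
  n <- n_patients(cohort)
  if (length(factors) == 0) {
    cells <- list(all = seq_len(n))
    counts <- data.frame(cell = "all", count = n, stringsAsFactors = FALSE)
    return(structure(list(factor_names = character(0),
                          assignments = data.frame(row.names = seq_len(n)),
                          cells = cells, counts = counts, n = n),
                     class = "stratum_set"))
  }
  stopifnot(all(vapply(factors, inherits, logical(1), "binary_factor")))
  lens <- vapply(factors, function(f) length(f$labels), integer(1))
  if (any(lens != n)) stop("factor length does not match cohort size")
  fnames <- vapply(factors, function(f) f$name, character(1))
  assign_df <- as.data.frame(stats::setNames(
    lapply(factors, function(f) f$labels), fnames), check.names = FALSE)
  key <- interaction(assign_df, sep = "/", drop = FALSE, lex.order = TRUE)
  cells <- split(seq_len(n), key, drop = FALSE)
  cells <- cells[lengths(cells) > 0 | TRUE]  # keep empty cells explicit
  cnt <- lengths(cells)
  lab_split <- strsplit(names(cells), "/", fixed = TRUE)
  counts <- as.data.frame(do.call(rbind, lab_split),
                          stringsAsFactors = FALSE)
  names(counts) <- fnames
  counts$count <- unname(cnt)
  structure(list(factor_names = fnames, assignments = assign_df,
                 cells = cells, counts = counts, n = n),
            class = "stratum_set")
}

#' @export
print.stratum_set <- function(x, ...) {
  cat("Stratum set over", length(x$factor_names), "factor(s):",
      paste(x$factor_names, collapse = " x "), "\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.stratum_set <- function(x, ...) x$counts

#' Write stratum counts to CSV (long format)
#'
#' One row per cell: the factor labels followed by the patient count — the
#' data behind a subgroup count heatmap.
#'
#' @param strata A `stratum_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_strata_counts <- function(strata, path) {
  utils::write.csv(strata$counts, path, row.names = FALSE)
  invisible(path)
}
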