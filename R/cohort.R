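#' Canonical radiomic feature categories
#'
#' The seven feature families used to group radiomic descriptors: first-order
#' intensity statistics, shape/morphology, and the five texture matrix
#' families (GLCM, GLSZM, GLRLM, NGTDM, GLDM).
#'
#' @return Character vector of the seven category names.
#' @export
feature_categories <- function() {
  c("FirstOrder", "Shape", "GLCM", "GLSZM", "GLRLM", "NGTDM", "GLDM")
}

#' Construct a radiomic survival cohort
#'
#' A `cohort` bundles a patient-by-feature matrix of non-negative radiomic
#' values with clinical covariates (age in years, gender, overall stage) and
#' right-censored survival outcomes (time in years, event indicator).
#' No missing values are permitted anywhere; rows with incomplete data must
#' be excluded before construction.
#'
#' @param patient_id Character vector of unique patient identifiers.
#' @param features Numeric matrix (patients x features) with unique column
#'   names; entries must be finite and non-negative.
#' @param categories Named character vector mapping each feature name to its
#'   category label.
#' @param age Numeric vector of ages in years (positive).
#' @param gender Character or factor with levels `female`/`male`
#'   (case-insensitive on input).
#' @param stage Character or factor with levels `I`, `II`, `IIIa`, `IIIb`.
#' @param time Numeric survival/follow-up times in years (strictly positive).
#' @param event Integer vector, 1 = death observed, 0 = censored.
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(patient_id, features, categories, age, gender, stage,
                       time, event) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  gender <- factor(tolower(as.character(gender)), levels = c("female", "male"))
  stage <- canonicalize_stage(stage)
  obj <- structure(list(
    patient_id = as.character(patient_id),
    features = features,
    categories = categories[colnames(features)],
    age = as.numeric(age),
    gender = gender,
    stage = stage,
    time = as.numeric(time),
    event = as.integer(event)
  ), class = "cohort")
  validate_cohort(obj)
  obj
}

canonicalize_stage <- function(stage) {
  s <- tolower(trimws(as.character(stage)))
  map <- c(i = "I", ii = "II", iiia = "IIIa", iiib = "IIIb")
  bad <- !(s %in% names(map)) & !is.na(s)
  if (any(bad)) {
    stop("unknown stage token(s): ", paste(unique(s[bad]), collapse = ", "),
         " (expected I, II, IIIa, IIIb)")
  }
  factor(map[s], levels = c("I", "II", "IIIa", "IIIb"))
}

#' Validate a cohort object
#'
#' Checks the structural invariants: matching lengths, unique ids and feature
#' names, no missing values, non-negative finite features, positive times,
#' and event coded 0/1.
#'
#' @param cohort A `cohort` object.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  n <- length(cohort$patient_id)
  if (n > 0 && anyDuplicated(cohort$patient_id)) {
    stop("patient_id values must be unique")
  }
  if (nrow(cohort$features) != n) {
    stop("feature matrix has ", nrow(cohort$features), " rows but ", n,
         " patient ids")
  }
  fn <- colnames(cohort$features)
  if (is.null(fn) && ncol(cohort$features) > 0) stop("features must be named")
  if (anyDuplicated(fn)) stop("feature names must be unique")
  if (length(cohort$categories) != ncol(cohort$features) ||
      any(is.na(cohort$categories))) {
    stop("every feature needs a non-missing category label")
  }
  for (fld in c("age", "gender", "stage", "time", "event")) {
    if (length(cohort[[fld]]) != n) stop("field '", fld, "' has wrong length")
    if (anyNA(cohort[[fld]])) stop("missing values in '", fld, "'")
  }
  if (anyNA(cohort$features) || any(!is.finite(cohort$features))) {
    stop("feature matrix contains missing or non-finite values")
  }
  if (any(cohort$features < 0)) stop("feature values must be non-negative")
  if (any(cohort$age <= 0)) stop("ages must be positive")
  if (any(cohort$time <= 0)) stop("all survival times must be > 0")
  if (!all(cohort$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  invisible(cohort)
}

#' Number of patients in a cohort
#' @param cohort A `cohort` object.
#' @return Integer patient count.
#' @export
n_patients <- function(cohort) length(cohort$patient_id)

#' @export
print.cohort <- function(x, ...) {
  cat("Radiomic survival cohort:", n_patients(x), "patients,",
      ncol(x$features), "features in",
      length(unique(x$categories)), "categories\n")
  cat("  events:", sum(x$event), " censored:", sum(1 - x$event), "\n")
  invisible(x)
}

#' Subset a cohort by patient rows
#' @param x A `cohort`.
#' @param i Row index (integer or logical).
#' @param ... Unused.
#' @return The restricted `cohort`.
#' @export
`[.cohort` <- function(x, i, ...) {
  new_cohort(x$patient_id[i], x$features[i, , drop = FALSE], x$categories,
             x$age[i], x$gender[i], x$stage[i], x$time[i], x$event[i])
}

#' Read a cohort from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `patient_id`,
#' one column per feature, then `age`, `gender`, `stage`, `time`, `event`.
#' Feature categories come from `schema`: either a named character vector
#' (feature -> category) or the path to a two-column CSV with columns
#' `feature,category`.
#'
#' @param path CSV file path.
#' @param schema Feature-category map (named vector or CSV path).
#' @param strict If `TRUE` (default) any missing cell is an error naming the
#'   patient and column; if `FALSE`, offending rows are dropped with a
#'   message (the exclusion rule used when assembling the original table).
#' @param time_unit `"years"` (default) or `"days"`; days are converted by
#'   division by 365.25.
#' @return A `cohort`.
#' @export
read_cohort <- function(path, schema, strict = TRUE,
                        time_unit = c("years", "days")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    sd <- utils::read.csv(schema, stringsAsFactors = FALSE)
    schema <- stats::setNames(sd$category, sd$feature)
  }
  meta <- c("patient_id", "age", "gender", "stage", "time", "event")
  missing_meta <- setdiff(meta, names(df))
  if (length(missing_meta)) {
    stop("cohort CSV lacks column(s): ", paste(missing_meta, collapse = ", "))
  }
  feat_cols <- setdiff(names(df), meta)
  unknown <- setdiff(feat_cols, names(schema))
  if (length(unknown)) {
    stop("feature(s) absent from schema: ", paste(unknown, collapse = ", "))
  }
  na_cells <- which(is.na(df), arr.ind = TRUE)
  if (nrow(na_cells) > 0) {
    desc <- paste0("patient ", df$patient_id[na_cells[, 1]], ", column '",
                   names(df)[na_cells[, 2]], "'", collapse = "; ")
    if (strict) stop("missing value(s): ", desc)
    drop <- unique(na_cells[, 1])
    message("dropping ", length(drop), " row(s) with missing data: ", desc)
    df <- df[-drop, , drop = FALSE]
  }
  feats <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(feats) <- NULL
  time <- df$time
  if (time_unit == "days") time <- time / 365.25
  new_cohort(df$patient_id, feats, schema[feat_cols], df$age, df$gender,
             df$stage, time, df$event)
}

#' Write a cohort to CSV
#'
#' Writes one row per patient with columns `patient_id`, the feature columns,
#' `age`, `gender`, `stage`, `time`, `event`. Gender and stage tokens are
#' written in canonical form. Optionally writes the feature-category schema
#' and a free-text sidecar (e.g. the generating parameters).
#'
#' @param cohort A `cohort`.
#' @param path Output CSV path.
#' @param schema_path Optional path for the two-column `feature,category`
#'   schema CSV.
#' @param sidecar Optional character vector written line-by-line to
#'   `<path>.meta.txt`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, schema_path = NULL, sidecar = NULL) {
  validate_cohort(cohort)
  df <- data.frame(patient_id = cohort$patient_id,
                   cohort$features,
                   age = cohort$age,
                   gender = as.character(cohort$gender),
                   stage = as.character(cohort$stage),
                   time = cohort$time,
                   event = cohort$event,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(schema_path)) {
    utils::write.csv(data.frame(feature = colnames(cohort$features),
                                category = unname(cohort$categories)),
                     schema_path, row.names = FALSE)
  }
  if (!is.null(sidecar)) writeLines(sidecar, paste0(path, ".meta.txt"))
  invisible(path)
}

#' Baseline characteristics summary of a cohort
#'
#' Computes the descriptive table reported for survival cohorts: age
#' mean/SD/median/IQR, gender and stage counts with percentages, median and
#' range of follow-up time, and event/censored counts.
#'
#' @param cohort A `cohort`.
#' @return An object of class `cohort_summary` (a list of summary fields).
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  n <- n_patients(cohort)
  q <- stats::quantile(cohort$age, c(0.25, 0.75), names = FALSE)
  structure(list(
    n = n,
    age_mean = mean(cohort$age),
    age_sd = stats::sd(cohort$age),
    age_median = stats::median(cohort$age),
    age_iqr = q,
    gender_counts = table(cohort$gender),
    gender_pct = 100 * table(cohort$gender) / n,
    stage_counts = table(cohort$stage),
    stage_pct = 100 * table(cohort$stage) / n,
    time_median = stats::median(cohort$time),
    time_range = range(cohort$time),
    n_events = sum(cohort$event),
    n_censored = sum(1L - cohort$event),
    event_pct = 100 * mean(cohort$event),
    censored_pct = 100 * mean(1 - cohort$event)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 3, ...) {
  cat("Patients (N):", x$n, "\n")
  cat(sprintf("Age, mean +/- SD (years): %.1f +/- %.1f\n", x$age_mean, x$age_sd))
  cat(sprintf("Age, median [IQR]: %.1f (%.1f-%.1f)\n", x$age_median,
              x$age_iqr[1], x$age_iqr[2]))
  for (g in names(x$gender_counts)) {
    cat(sprintf("Gender %s: %d (%.1f%%)\n", g, x$gender_counts[[g]],
                x$gender_pct[[g]]))
  }
  for (s in names(x$stage_counts)) {
    cat(sprintf("Stage %s: %d (%.1f%%)\n", s, x$stage_counts[[s]],
                x$stage_pct[[s]]))
  }
  cat(sprintf("Survival time, median (range) years: %.2f (%.2f-%.2f)\n",
              x$time_median, x$time_range[1], x$time_range[2]))
  cat(sprintf("Deaths: %d (%.1f%%); Censored: %d (%.1f%%)\n",
              x$n_events, x$event_pct, x$n_censored, x$censored_pct))
  invisible(x)
}
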