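#' SMOTE-style balancing of survival subgroups
#'
#' Synthetic minority oversampling adapted to rows that carry right-censored
#' survival outcomes. Each synthetic row interpolates a minority "seed" row
#' and one of its k nearest minority neighbours in standardized radiomic
#' feature space, with a uniform weight `w`: features, numeric covariates
#' and survival time are all interpolated with the same `w`; categorical
#' covariates are copied from the seed parent. Because plain interpolation
#' is undefined for the event indicator, generation is (by default)
#' stratified within event status: synthetic rows inherit the event status
#' of their stratum, which preserves each class's censoring structure.
#'
#' Balanced sets are exploratory devices for checking the stability of
#' stratification patterns under balanced subgroup composition; they must
#' not feed hazard-ratio estimation or the upstream feature ranking.
#'
#' @param cohort A [new_cohort()] object.
#' @param class_labels Character or factor with one class label per patient
#'   (e.g. the stratum-cell membership); at least 2 classes.
#' @param k Number of nearest neighbours considered (default 5); reduced
#'   with a warning when a stratum is smaller than `k + 1`.
#' @param target `"majority"` (default) equalizes every class to the largest
#'   class size; alternatively a named integer vector of per-class target
#'   sizes.
#' @param strata_mode `"within-event"` (default) generates separately inside
#'   each event-status stratum of a class, allocating synthetic rows
#'   proportionally to stratum sizes; `"pooled"` treats the class as one
#'   stratum and draws the synthetic event status from the seed parent.
#' @param size_one What to do when a stratum that would receive synthetic
#'   rows has a single member (no neighbour to interpolate): `"error"`
#'   (default) stops; `"skip"` reallocates that stratum's quota to the
#'   class's other strata with a warning.
#' @param seed Integer seed.
#' @return An object of class `balanced_set`: a data frame `data` holding
#'   original and synthetic rows (feature columns, `age`, `gender`, `stage`,
#'   `time`, `event`, `class`, `synthetic`, `parent1`, `parent2`, `w`), the
#'   per-class target sizes, and the configuration.
#' @export
smote_balance <- function(cohort, class_labels, k = 5,
                          target = "majority",
                          strata_mode = c("within-event", "pooled"),
                          size_one = c("error", "skip"),
                          seed = 1) {
  validate_cohort(cohort)
  strata_mode <- match.arg(strata_mode)
  size_one <- match.arg(size_one)
  stopifnot(k >= 1)
  cls <- factor(class_labels)
  if (nlevels(cls) < 2) stop("need at least 2 classes to balance")
  if (length(cls) != n_patients(cohort)) {
    stop("class_labels length does not match cohort size")
  }
  sizes <- table(cls)
  if (identical(target, "majority")) {
    target_sizes <- stats::setNames(rep(max(sizes), nlevels(cls)),
                                    levels(cls))
  } else {
    stopifnot(!is.null(names(target)),
              all(levels(cls) %in% names(target)))
    target_sizes <- target[levels(cls)]
    if (any(target_sizes < sizes)) {
      stop("target size below current class size for: ",
           paste(levels(cls)[target_sizes < sizes], collapse = ", "))
    }
  }

  base <- data.frame(patient_id = cohort$patient_id,
                     cohort$features,
                     age = cohort$age,
                     gender = as.character(cohort$gender),
                     stage = as.character(cohort$stage),
                     time = cohort$time,
                     event = cohort$event,
                     class = as.character(cls),
                     synthetic = FALSE,
                     parent1 = NA_character_, parent2 = NA_character_,
                     w = NA_real_,
                     check.names = FALSE, stringsAsFactors = FALSE)
  feat_names <- colnames(cohort$features)

  set.seed(seed)
  synth_rows <- list()
  synth_counter <- 0L
  for (cl in levels(cls)) {
    deficit <- target_sizes[[cl]] - sizes[[cl]]
    if (deficit <= 0) next
    members <- which(cls == cl)
    strata <- if (strata_mode == "within-event") {
      split(members, cohort$event[members])
    } else {
      list(all = members)
    }
    strata <- strata[lengths(strata) > 0]
    if (any(lengths(strata) == 1)) {
      if (size_one == "error") {
        stop("stratum of size 1 in class '", cl,
             "' cannot be oversampled (no neighbour to interpolate)")
      }
      warning("class '", cl, "': skipping size-1 stratum, reallocating ",
              "its quota", call. = FALSE)
      strata <- strata[lengths(strata) >= 2]
      if (length(strata) == 0) {
        stop("class '", cl, "' has no stratum with >= 2 rows to ",
             "oversample from")
      }
    }
    # proportional allocation with largest remainders
    raw <- deficit * lengths(strata) / sum(lengths(strata))
    alloc <- floor(raw)
    rem <- deficit - sum(alloc)
    if (rem > 0) {
      ord <- order(raw - alloc, decreasing = TRUE)
      alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
    }
    for (si in seq_along(strata)) {
      m <- alloc[[si]]
      if (m == 0) next
      rows <- strata[[si]]
      k_eff <- k
      if (length(rows) < k + 1) {
        k_eff <- length(rows) - 1L
        warning("class '", cl, "': stratum smaller than k+1, reducing k to ",
                k_eff, call. = FALSE)
      }
      xs <- cohort$features[rows, , drop = FALSE]
      mu <- colMeans(xs)
      sdv <- apply(xs, 2, stats::sd)
      sdv[sdv == 0] <- 1
      xz <- sweep(sweep(xs, 2, mu), 2, sdv, "/")
      dd <- as.matrix(stats::dist(xz))
      diag(dd) <- Inf
      nn <- matrix(apply(dd, 1, function(d) order(d)[seq_len(k_eff)]),
                   ncol = k_eff, byrow = TRUE)
      seeds <- sample(seq_along(rows), m, replace = TRUE)
      picks <- vapply(seeds, function(s) {
        nbrs <- nn[s, , drop = TRUE]
        nbrs[sample.int(k_eff, 1)]
      }, integer(1))
      ws <- stats::runif(m)
      for (j in seq_len(m)) {
        p1 <- rows[seeds[j]]; p2 <- rows[picks[j]]
        w <- ws[j]
        synth_counter <- synth_counter + 1L
        row <- base[p1, , drop = FALSE]
        row$patient_id <- sprintf("S%05d", synth_counter)
        row[feat_names] <- (1 - w) * cohort$features[p1, ] +
          w * cohort$features[p2, ]
        row$age <- (1 - w) * cohort$age[p1] + w * cohort$age[p2]
        row$time <- (1 - w) * cohort$time[p1] + w * cohort$time[p2]
        row$event <- cohort$event[p1]  # stratum-inherited (equal within)
        row$synthetic <- TRUE
        row$parent1 <- cohort$patient_id[p1]
        row$parent2 <- cohort$patient_id[p2]
        row$w <- w
        synth_rows[[synth_counter]] <- row
      }
    }
  }
  data <- if (length(synth_rows)) {
    rbind(base, do.call(rbind, synth_rows))
  } else {
    base
  }
  rownames(data) <- NULL
  structure(list(data = data, target_sizes = target_sizes,
                 feature_names = feat_names,
                 config = list(k = k, target = target,
                               strata_mode = strata_mode,
                               size_one = size_one, seed = seed)),
            class = "balanced_set")
}

#' @export
print.balanced_set <- function(x, ...) {
  tab <- table(x$data$class, x$data$synthetic)
  cat("SMOTE-balanced set:", sum(!x$data$synthetic), "original +",
      sum(x$data$synthetic), "synthetic rows\n")
  print(tab)
  invisible(x)
}

#' Write a balanced set to CSV
#'
#' Includes the `synthetic` flag, parent ids and interpolation weight so
#' synthetic provenance is carried with the data.
#'
#' @param balanced A `balanced_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_balanced_set <- function(balanced, path) {
  utils::write.csv(balanced$data, path, row.names = FALSE)
  invisible(path)
}
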