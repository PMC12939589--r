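#' Kaplan-Meier product-limit estimate
#'
#' Computes the survival function from right-censored data as
#' `S(t) = prod_{t_j <= t} (1 - d_j / n_j)` over the distinct event times
#' `t_j`, with `d_j` events among `n_j` at risk. Observations censored at an
#' event time are counted at risk for that time (the standard convention:
#' at ties, censoring happens after events). The cumulative Greenwood sum
#' `sum d_j / (n_j (n_j - d_j))` is carried for variance estimation.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return An object of class `km_curve`: a list with a step-function table
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `surv`, `greenwood`) over the
#'   distinct event times, plus the sample size `n`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (length(time) == 0) stop("empty input")
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  event <- as.integer(event)
  tj <- sort(unique(time[event == 1]))
  if (length(tj) == 0) {
    tab <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), n_censor = integer(0),
                      surv = numeric(0), greenwood = numeric(0))
    return(structure(list(table = tab, n = length(time)),
                     class = "km_curve"))
  }
  n_risk <- vapply(tj, function(t) sum(time >= t), integer(1))
  n_event <- vapply(tj, function(t) sum(time == t & event == 1L), integer(1))
  n_censor <- vapply(tj, function(t) sum(time == t & event == 0L), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw_terms <- ifelse(n_risk > n_event,
                     n_event / (n_risk * (n_risk - n_event)), Inf)
  tab <- data.frame(time = tj, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv,
                    greenwood = cumsum(gw_terms))
  structure(list(table = tab, n = length(time)), class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step evaluation: `S(t) = 1` before the first event time.
#'
#' @param curve A `km_curve`.
#' @param t Times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  tab <- curve$table
  if (nrow(tab) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, tab$time)
  ifelse(idx == 0, 1, tab$surv[pmax(idx, 1)])
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest event time at which the estimated survival drops to 0.5 or
#' below; `NA` if the curve never reaches 0.5.
#'
#' @param curve A `km_curve`.
#' @return Numeric median survival time or `NA`.
#' @export
km_median_survival <- function(curve) {
  tab <- curve$table
  hit <- which(tab$surv <= 0.5)
  if (length(hit) == 0) return(NA_real_)
  tab$time[hit[1]]
}

#' Greenwood confidence bands on the log-log scale
#'
#' Confidence intervals for `S(t)` built from Greenwood's variance via the
#' complementary log-log transform `log(-log S)`, which keeps the bands in
#' `[0, 1]`. Segments with `S = 1` get the degenerate interval `[1, 1]`;
#' `S = 0` gets `[0, 0]`.
#'
#' @param curve A `km_curve`.
#' @param level Confidence level in `(0, 1)` (default 0.95).
#' @return The `km_curve` with `lower` and `upper` columns added to its
#'   table and the `level` recorded.
#' @export
greenwood_ci <- function(curve, level = 0.95) {
  stopifnot(inherits(curve, "km_curve"), level > 0, level < 1)
  tab <- curve$table
  z <- stats::qnorm(1 - (1 - level) / 2)
  s <- tab$surv
  lower <- upper <- s
  ok <- s > 0 & s < 1 & is.finite(tab$greenwood)
  se_cll <- sqrt(tab$greenwood[ok]) / abs(log(s[ok]))
  lower[ok] <- s[ok]^exp(z * se_cll)
  upper[ok] <- s[ok]^exp(-z * se_cll)
  lower[s == 0] <- 0
  upper[s == 0] <- 0
  tab$lower <- pmin(pmax(lower, 0), 1)
  tab$upper <- pmin(pmax(upper, 0), 1)
  curve$table <- tab
  curve$level <- level
  curve
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$table$n_event),
      "\n")
  med <- km_median_survival(x)
  cat("  median survival:", if (is.na(med)) "not reached"
      else sprintf("%.3g", med), "\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, col = "steelblue", add = FALSE,
                          xlab = "time (years)", ylab = "survival",
                          main = "Kaplan-Meier estimate", ...) {
  tab <- x$table
  tt <- c(0, tab$time)
  ss <- c(1, tab$surv)
  if (!add) {
    graphics::plot(tt, ss, type = "s", ylim = c(0, 1), col = col,
                   xlab = xlab, ylab = ylab, main = main, lwd = 2, ...)
  } else {
    graphics::lines(tt, ss, type = "s", col = col, lwd = 2, ...)
  }
  if (!is.null(tab$lower)) {
    graphics::lines(tt, c(1, tab$lower), type = "s", col = col, lty = 3)
    graphics::lines(tt, c(1, tab$upper), type = "s", col = col, lty = 3)
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank: at each distinct event time the observed
#' events in group 1 are compared with the expectation under the null of a
#' common hazard, with hypergeometric variance; the squared standardized sum
#' is referred to a chi-square distribution with 1 degree of freedom.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping (factor, character, or logical); both
#'   groups must be non-empty and at least one event must occur.
#' @return An object of class `logrank_result`: `statistic`, `df`,
#'   `p_value`, per-group `observed` and `expected` event counts, and the
#'   group names.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2) {
    stop("log-rank test requires exactly 2 non-empty groups, got ",
         nlevels(g))
  }
  event <- as.integer(event)
  if (sum(event) < 1) stop("no events observed")
  tj <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- numeric(length(tj))
  g1 <- levels(g)[1]
  for (j in seq_along(tj)) {
    at_risk <- time >= tj[j]
    nj <- sum(at_risk)
    n1j <- sum(at_risk & g == g1)
    dj <- sum(time == tj[j] & event == 1L)
    d1j <- sum(time == tj[j] & event == 1L & g == g1)
    o1[j] <- d1j
    e1[j] <- dj * n1j / nj
    v[j] <- if (nj > 1) dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
            else 0
  }
  O1 <- sum(o1); E1 <- sum(e1); V <- sum(v)
  stat <- if (V > 0) (O1 - E1)^2 / V else 0
  total_obs <- sum(event)
  structure(list(statistic = stat, df = 1L,
                 p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                 observed = stats::setNames(c(O1, total_obs - O1), levels(g)),
                 expected = stats::setNames(c(E1, total_obs - E1), levels(g)),
                 groups = levels(g)),
            class = "logrank_result")
}

#' Format a p-value for reporting
#'
#' Two significant figures, floored at `"<0.0001"`.
#'
#' @param p Numeric p-value.
#' @return Character rendering.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-4, "<0.0001", signif(p, 2))
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %s\n",
              x$statistic, x$df, format_pvalue(x$p_value)))
  df <- data.frame(group = x$groups, observed = unname(x$observed),
                   expected = round(unname(x$expected), 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Compare survival between the two levels of a binary factor
#'
#' Builds one figure-panel record: per-group Kaplan-Meier curves with
#' Greenwood bands plus the two-group log-rank test, optionally restricted
#' to a subset of patients (a stratum cell). If either group is empty after
#' restriction the panel is skipped with a message and `NULL` is returned.
#'
#' @param time,event Survival outcome vectors.
#' @param grouping A [binary_factor()] labelled on the same patients.
#' @param within Optional logical or integer index restricting the
#'   comparison (e.g. one cell of a [build_strata()] result).
#' @param label Panel label for reporting.
#' @param level Confidence level for the bands (default 0.95).
#' @return An object of class `km_panel`, or `NULL` if skipped.
#' @export
compare_strata <- function(time, event, grouping, within = NULL,
                           label = grouping$name, level = 0.95) {
  stopifnot(inherits(grouping, "binary_factor"))
  idx <- seq_along(time)
  if (!is.null(within)) idx <- idx[within]
  labs <- grouping$labels[idx]
  if (any(table(factor(labs, levels = grouping$levels)) == 0)) {
    message("panel '", label, "' skipped: empty group after restriction")
    return(NULL)
  }
  curves <- lapply(grouping$levels, function(lv) {
    sel <- idx[labs == lv]
    greenwood_ci(km_estimate(time[sel], event[sel]), level)
  })
  names(curves) <- grouping$levels
  lr <- logrank_test(time[idx], event[idx], labs)
  structure(list(
    label = label,
    groups = grouping$levels,
    curves = curves,
    n = vapply(curves, function(cv) cv$n, numeric(1)),
    events = vapply(curves, function(cv) sum(cv$table$n_event), numeric(1)),
    median_survival = vapply(curves, km_median_survival, numeric(1)),
    logrank = lr
  ), class = "km_panel")
}

#' @export
print.km_panel <- function(x, ...) {
  cat("KM panel:", x$label, "\n")
  df <- data.frame(group = x$groups, n = unname(x$n),
                   events = unname(x$events),
                   median_survival = round(unname(x$median_survival), 3))
  print(df, row.names = FALSE)
  cat(sprintf("  log-rank chi-square = %.4g, p = %s\n",
              x$logrank$statistic, format_pvalue(x$logrank$p_value)))
  invisible(x)
}

#' @export
plot.km_panel <- function(x, cols = c("steelblue", "darkorange"), ...) {
  for (i in seq_along(x$curves)) {
    plot(x$curves[[i]], col = cols[i], add = i > 1,
         main = x$label, ...)
  }
  graphics::legend("topright", legend = x$groups, col = cols, lwd = 2,
                   bty = "n")
  graphics::mtext(sprintf("log-rank p = %s",
                          format_pvalue(x$logrank$p_value)), side = 3,
                  line = -1.5, adj = 0.05, cex = 0.9)
  invisible(x)
}

# Flatten a list of km_panel records into the tabular export used by the
# pipeline (one row per group per panel).
panels_to_data_frame <- function(panels) {
  rows <- lapply(panels, function(p) {
    if (is.null(p)) return(NULL)
    data.frame(panel = p$label, group = p$groups, n = unname(p$n),
               events = unname(p$events),
               median_survival = unname(p$median_survival),
               statistic = p$logrank$statistic,
               p_value = p$logrank$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
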