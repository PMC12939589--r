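# Independent brute-force oracles used to validate the package's survival
# primitives. These deliberately re-derive each quantity from first
# principles (risk-set loops, explicit rank formulas, Newton iterations)
# rather than calling the code paths they check.

# Product-limit estimate by explicit risk-set enumeration.
oracle_km <- function(time, event) {
  tj <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tj, surv = NA_real_, greenwood = NA_real_)
  gw <- 0
  for (i in seq_along(tj)) {
    n_at <- sum(time >= tj[i])
    d <- sum(time == tj[i] & event == 1)
    s <- s * (1 - d / n_at)
    gw <- gw + if (n_at > d) d / (n_at * (n_at - d)) else Inf
    out$surv[i] <- s
    out$greenwood[i] <- gw
  }
  out
}

# Two-group log-rank statistic by explicit risk-set enumeration.
oracle_logrank <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  tj <- sort(unique(time[event == 1]))
  num <- 0; var <- 0
  for (t in tj) {
    at <- time >= t
    nj <- sum(at); n1 <- sum(at & group == g1)
    dj <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    num <- num + d1 - dj * n1 / nj
    if (nj > 1) var <- var + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  num^2 / var
}

# Average-rank Spearman correlation from the definition (Pearson on ranks
# computed by explicit tie-averaging).
oracle_spearman <- function(a, b) {
  avg_rank <- function(v) {
    vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
  }
  ra <- avg_rank(a); rb <- avg_rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Newton-Raphson on the single-covariate Cox partial likelihood with
# Breslow tie handling.
oracle_cox_newton <- function(x, time, event, tol = 1e-12, maxit = 100) {
  beta <- 0
  tj <- sort(unique(time[event == 1]))
  for (it in seq_len(maxit)) {
    U <- 0; I <- 0
    for (t in tj) {
      at <- time >= t
      d <- sum(time == t & event == 1)
      sx <- sum(x[time == t & event == 1])
      w <- exp(beta * x[at])
      s0 <- sum(w); s1 <- sum(w * x[at]); s2 <- sum(w * x[at]^2)
      U <- U + sx - d * s1 / s0
      I <- I + d * (s2 / s0 - (s1 / s0)^2)
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# Small standard cohort specs reused across tests.
tiny_blocks <- c(FirstOrder = 3, Shape = 3, GLCM = 3, GLSZM = 3,
                 GLRLM = 3, NGTDM = 5, GLDM = 3)

tiny_spec <- function(n = 80, seed = 1, ...) {
  cohort_spec(n_patients = n, block_sizes = tiny_blocks, seed = seed, ...)
}

# Hand-built 5-patient cohort for I/O and summary tests.
toy_cohort <- function(n = 5) {
  feats <- matrix(seq_len(2 * n) / 2, n, 2,
                  dimnames = list(NULL, c("Busyness", "Shape_01")))
  new_cohort(paste0("P", seq_len(n)), feats,
             c(Busyness = "NGTDM", Shape_01 = "Shape"),
             age = seq(60, 60 + (n - 1) * 5, by = 5),
             gender = rep(c("male", "female"), length.out = n),
             stage = rep(c("I", "II", "IIIa", "IIIb"), length.out = n),
             time = seq_len(n) / 2, event = rep(c(1L, 0L), length.out = n))
}
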