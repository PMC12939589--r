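make_feature_cohort <- function(feats) {
  n <- nrow(feats)
  new_cohort(paste0("P", seq_len(n)), feats,
             setNames(rep("NGTDM", ncol(feats)), colnames(feats)),
             age = rep(65, n), gender = rep("male", n),
             stage = rep("I", n), time = seq_len(n), event = rep(1L, n))
}

test_that("Spearman correlation is invariant under monotone transforms", {
  set.seed(31)
  a <- rexp(20)
  feats <- cbind(A = a, B = exp(a), C = max(a) + 1 - a)
  co <- make_feature_cohort(feats)
  rho <- spearman_matrix(co, c("A", "B", "C"))
  expect_equal(rho["A", "B"], 1)
  expect_equal(rho["A", "C"], -1)
  expect_equal(rho, t(rho))
  expect_equal(unname(diag(rho)), rep(1, 3))
})

test_that("tied data match the brute-force average-rank oracle", {
  a <- c(1, 2, 2, 3, 3, 3)
  b <- c(2, 1, 4, 4, 5, 6)
  co <- make_feature_cohort(cbind(A = a, B = b))
  rho <- spearman_matrix(co, c("A", "B"))
  expect_equal(rho["A", "B"], oracle_spearman(a, b), tolerance = 1e-12)
})

test_that("zero-variance features are flagged as undefined", {
  co <- make_feature_cohort(cbind(A = c(1, 2, 3, 4), B = rep(2, 4)))
  expect_warning(rho <- spearman_matrix(co, c("A", "B")), "zero-variance")
  expect_true(is.na(rho["A", "B"]))
})

test_that("RSS is the mean absolute correlation with the rest of the set", {
  rho <- matrix(c(1, 0.6, -0.8,
                  0.6, 1, 0.3,
                  -0.8, 0.3, 1), 3, 3,
                dimnames = list(c("f", "g", "h"), c("f", "g", "h")))
  expect_equal(compute_rss(rho, "f"), 0.7)
  expect_equal(compute_rss(rho, "g"), 0.45)
  # a two-feature set: RSS of each is |rho| between them
  rho2 <- rho[1:2, 1:2]
  expect_equal(compute_rss(rho2, "f"), 0.6)
  expect_equal(compute_rss(rho2, "g"), 0.6)
  expect_error(compute_rss(rho[1, 1, drop = FALSE], "f"), "at least 2")
})

test_that("RSS values recompute from the Spearman matrix and lie in [0,1]", {
  co <- generate_cohort(tiny_spec(n = 150, seed = 32))
  ngtdm <- names(co$categories)[co$categories == "NGTDM"]
  rho <- spearman_matrix(co, ngtdm)
  rss <- vapply(ngtdm, function(f) compute_rss(rho, f), numeric(1))
  expect_true(all(rss >= 0 & rss <= 1))
  # mean RSS equals mean off-diagonal |rho|
  expect_equal(mean(rss), mean(abs(rho[row(rho) != col(rho)])),
               tolerance = 1e-12)
  # invariance under a strictly monotone transform of one feature
  co2 <- co
  co2$features[, ngtdm[1]] <- exp(co2$features[, ngtdm[1]])
  rho2 <- spearman_matrix(co2, ngtdm)
  expect_equal(rho2, rho, tolerance = 1e-12)
})

test_that("the representative is the planted block's most central feature", {
  co <- generate_cohort(tiny_spec(n = 300, seed = 33))
  fr <- rank_biomarkers(co, n_runs = 4, nlambda = 10, seed = 17)
  rep <- suppressWarnings(select_representative(fr, co))
  expect_s3_class(rep, "correlation_report")
  expect_true(rep$representative %in% rep$features)
  # the chosen feature attains the maximal RSS
  expect_equal(max(rep$rss), rep$rss[[rep$representative]])
})

test_that("mutually uncorrelated candidates trigger a low-redundancy warning", {
  set.seed(34)
  feats <- matrix(rexp(200 * 4), 200, 4,
                  dimnames = list(NULL, c("A", "B", "C", "D")))
  co <- make_feature_cohort(feats)
  co$time <- rexp(200); co$event <- rep(1L, 200)
  fr <- structure(list(counts = c(A = 5L, B = 5L, C = 5L, D = 5L),
                       failures = c(A = 0L, B = 0L, C = 0L, D = 0L),
                       total_models = 5L,
                       ranks = radstrat:::competition_rank(
                         c(A = 5L, B = 5L, C = 5L, D = 5L)),
                       categories = co$categories,
                       config = list()), class = "freq_ranking")
  expect_warning(rep <- select_representative(fr, co), "low redundancy")
  expect_true(rep$representative %in% c("A", "B", "C", "D"))
})

test_that("RSS ties break by frequency then name", {
  # two perfectly correlated candidates: equal RSS, unequal counts
  set.seed(35)
  a <- rexp(50)
  co <- make_feature_cohort(cbind(A = a, B = 2 * a, C = rexp(50)))
  fr <- structure(list(counts = c(A = 3L, B = 7L, C = 7L),
                       failures = c(A = 0L, B = 0L, C = 0L),
                       total_models = 7L,
                       ranks = radstrat:::competition_rank(
                         c(A = 3L, B = 7L, C = 7L)),
                       categories = co$categories,
                       config = list()), class = "freq_ranking")
  rep <- suppressWarnings(select_representative(fr, co))
  # candidate set is the {B, C} tie group; equal-RSS tie resolved by count
  expect_setequal(rep$features, c("B", "C"))
})
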