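test_that("KM without censoring equals one minus the empirical CDF", {
  time <- c(1, 2, 3)
  km <- km_estimate(time, c(1, 1, 1))
  expect_equal(km$table$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km_survival_at(km, c(0.5, 1, 2.5, 3)),
               c(1, 2 / 3, 1 / 3, 0))
  set.seed(61)
  t2 <- rexp(40)
  km2 <- km_estimate(t2, rep(1, 40))
  ecdf2 <- ecdf(t2)
  at <- sort(t2)
  expect_equal(km_survival_at(km2, at), 1 - ecdf2(at), tolerance = 1e-12)
})

test_that("an all-censored sample keeps survival at one", {
  km <- km_estimate(c(1, 2, 5), c(0, 0, 0))
  expect_equal(nrow(km$table), 0)
  expect_equal(km_survival_at(km, c(0.1, 10)), c(1, 1))
  expect_true(is.na(km_median_survival(km)))
})

test_that("the mixed toy set matches the brute-force product-limit oracle", {
  time <- c(1, 2, 3, 3, 4)
  event <- c(1, 0, 1, 1, 0)
  km <- km_estimate(time, event)
  orc <- oracle_km(time, event)
  expect_equal(km$table$time, orc$time)
  expect_equal(km$table$surv, orc$surv, tolerance = 1e-15)
  expect_equal(km$table$greenwood, orc$greenwood, tolerance = 1e-15)
  # censoring at an event time keeps the row at risk for that time
  expect_equal(km$table$n_risk, c(5, 3))
  # and the reference implementation agrees
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km_survival_at(km, sf$time[sf$n.event > 0]),
               sf$surv[sf$n.event > 0], tolerance = 1e-12)
})

test_that("Greenwood bands are degenerate at S=1 and widen as risk shrinks", {
  time <- c(1, 2, 3, 3, 4, 6, 7)
  event <- c(1, 0, 1, 1, 0, 1, 1)
  km <- greenwood_ci(km_estimate(time, event), 0.95)
  tab <- km$table
  expect_equal(tab$greenwood,
               oracle_km(time, event)$greenwood, tolerance = 1e-15)
  # cumulative Greenwood sum is non-decreasing
  expect_true(all(diff(tab$greenwood) >= 0))
  expect_true(all(tab$lower <= tab$surv & tab$surv <= tab$upper))
  expect_true(all(tab$lower >= 0 & tab$upper <= 1))
  # an all-censored prefix keeps S=1 with a [1,1] band
  km2 <- greenwood_ci(km_estimate(c(1, 2), c(0, 0)))
  expect_equal(nrow(km2$table), 0)
})

test_that("identical groups give a zero log-rank statistic and p = 1", {
  time <- rep(c(1, 2, 3, 4), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  group <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_equal(sum(lr$expected), sum(event))
})

test_that("an 8-patient instance matches the brute-force O-E/V oracle", {
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- c("a", "b", "a", "b", "a", "b", "a", "b")
  lr <- logrank_test(time, event, group)
  expect_equal(lr$statistic, oracle_logrank(time, event, group),
               tolerance = 1e-12)
  # reference implementation agreement
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-8)
  # expected counts sum to total observed events
  expect_equal(sum(lr$expected), sum(event))
})

test_that("the analytic p agrees with a permutation reference", {
  set.seed(101)
  n <- 16
  group <- rep(c("a", "b"), each = 8)
  time <- round(rexp(n, ifelse(group == "a", 1, 1.8)), 3) + 0.01
  event <- rbinom(n, 1, 0.85)
  obs <- oracle_logrank(time, event, group)
  set.seed(62)
  perm <- replicate(1e4, oracle_logrank(time, event, sample(group)))
  p_perm <- mean(perm >= obs - 1e-12)
  p_analytic <- logrank_test(time, event, group)$p_value
  expect_lt(abs(p_analytic - p_perm), 0.03)
})

test_that("log-rank is invariant to relabeling and monotone time transforms", {
  set.seed(63)
  time <- rexp(40) + 0.1
  event <- rbinom(40, 1, 0.8)
  group <- rep(c("a", "b"), 20)
  lr1 <- logrank_test(time, event, group)
  lr2 <- logrank_test(time, event, ifelse(group == "a", "z", "y"))
  lr3 <- logrank_test(time^2, event, group)  # strictly monotone on t > 0
  expect_equal(lr1$statistic, lr2$statistic, tolerance = 1e-12)
  expect_equal(lr1$statistic, lr3$statistic, tolerance = 1e-12)
})

test_that("doubling the cohort doubles O and E per group", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  lr1 <- logrank_test(time, event, group)
  lr2 <- logrank_test(rep(time, 2), rep(event, 2), rep(group, 2))
  expect_equal(unname(lr2$observed), 2 * unname(lr1$observed))
  expect_equal(unname(lr2$expected), 2 * unname(lr1$expected),
               tolerance = 1e-12)
  expect_equal(lr2$statistic,
               oracle_logrank(rep(time, 2), rep(event, 2), rep(group, 2)),
               tolerance = 1e-12)
})

test_that("degenerate group inputs are rejected", {
  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "2 non-empty")
  expect_error(logrank_test(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("compare_strata builds panels and skips empty groups", {
  co <- generate_cohort(tiny_spec(n = 120, seed = 64))
  f_bio <- binarize_biomarker(co, "Busyness")
  panel <- compare_strata(co$time, co$event, f_bio, label = "biomarker")
  expect_s3_class(panel, "km_panel")
  expect_equal(sum(panel$n), 120)
  expect_named(panel$curves, c("Low", "High"))
  expect_s3_class(panel$logrank, "logrank_result")
  # restriction that empties one side is skipped with a message
  expect_message(
    skipped <- compare_strata(co$time, co$event, f_bio,
                              within = f_bio$labels == "Low",
                              label = "degenerate"),
    "skipped")
  expect_null(skipped)
})

test_that("planted biomarker separates survival within stage, not vice versa", {
  co <- generate_cohort(cohort_spec(seed = 65))
  f_stage <- binarize_stage(co$stage)
  f_bio <- binarize_biomarker(co, "Busyness")
  for (lv in c("Low", "High")) {
    p_bio <- compare_strata(co$time, co$event, f_bio,
                            within = f_stage$labels == lv)$logrank$p_value
    expect_lt(p_bio, 0.01)
    p_stage <- compare_strata(co$time, co$event, f_stage,
                              within = f_bio$labels == lv)$logrank$p_value
    expect_gt(p_stage, 0.05)
  }
})

test_that("panel records flatten to the tabular export", {
  co <- generate_cohort(tiny_spec(n = 80, seed = 66))
  f_bio <- binarize_biomarker(co, "Busyness")
  f_age <- binarize_age(co$age)
  panels <- list(compare_strata(co$time, co$event, f_bio, label = "bio"),
                 compare_strata(co$time, co$event, f_age, label = "age"),
                 NULL)
  df <- radstrat:::panels_to_data_frame(panels)
  expect_equal(nrow(df), 4)
  expect_setequal(unique(df$panel), c("bio", "age"))
  expect_true(all(c("n", "events", "median_survival", "statistic",
                    "p_value") %in% names(df)))
})
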