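test_that("group comparison picks the documented test branches", {
  set.seed(3)
  base <- rnorm(20, 10, 2)
  tab <- data.frame(group = rep(c("failure", "control"), each = 20),
                    v = c(base, sample(base)))
  gc <- compare_groups(tab, "v")
  expect_equal(gc$test, "t")
  expect_gte(gc$p_value, 0.99)  # identical distributions
  # skewed data falls back to Mann-Whitney
  tab$w <- c(exp(rnorm(20, 0, 2)), exp(rnorm(20, 0, 2)))
  expect_equal(compare_groups(tab, "w")$test, "mann-whitney")
  # both groups constant: exact equality check
  tab$c1 <- rep(5, 40)
  expect_equal(compare_groups(tab, "c1")$p_value, 1)
  tab$c2 <- rep(c(5, 6), each = 20)
  expect_equal(compare_groups(tab, "c2")$p_value, 0)
})

test_that("categorical and ordinal comparisons use chi-square and rank-sum", {
  tab <- data.frame(group = rep(c("failure", "control"), each = 10),
                    site = rep(c("hypopharynx", "larynx"), times = 10))
  gc <- compare_groups(tab, "site")
  expect_equal(gc$test, "chi-square")
  # perfectly separated 2x2 table (10,0 / 0,10): chi-square statistic = 20
  sep <- data.frame(group = rep(c("failure", "control"), each = 10),
                    cat = rep(c("a", "b"), each = 10))
  gc <- compare_groups(sep, "cat")
  expect_equal(gc$statistic, 20)
  expect_lt(gc$p_value, 0.001)
  # ordered stages use the rank-sum branch by default
  tab$stage <- factor(rep(0:3, 5), levels = 0:3, ordered = TRUE)
  expect_equal(compare_groups(tab, "stage")$test, "rank-sum")
})

test_that("group comparison has power under the published effect size", {
  hits <- vapply(1:1000, function(i) {
    tab <- simulate_cohort(cohort_spec(seed = 40000 + i))
    compare_groups(tab, "ADCmean")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("AUC equals exhaustive pair counting and handles edge cases", {
  # 6-point worked set: 8 of 9 pairs concordant
  vals <- c(3.0, 2.5, 2.0, 1.0, 1.5, 2.2)
  labs <- rep(c("failure", "control"), each = 3)
  r <- roc_analysis(vals, labs)
  expect_equal(r$auc, 8 / 9)
  expect_equal(r$auc, auc_pair_oracle(vals, labs))
  # random small inputs, with ties: ranking identity == brute force
  set.seed(66)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    v <- round(rnorm(n, 1, 0.5), 1)
    l <- sample(c("failure", "control"), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(roc_analysis(v, l)$auc, auc_pair_oracle(v, l))
  }
  # perfect separation
  sep <- roc_analysis(c(5, 6, 7, 1, 2, 3), rep(c("failure", "control"), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)
  # uninformative marker
  set.seed(10)
  big <- roc_analysis(rnorm(2000), rep(c("failure", "control"), 1000))
  expect_lt(abs(big$auc - 0.5), 0.05)
  expect_error(roc_analysis(1:5, rep("failure", 5)),
               class = "ivimprog_input_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:10) {
    v <- rnorm(40)
    l <- sample(c("failure", "control"), 40, replace = TRUE,
                prob = c(0.6, 0.4))
    if (length(unique(l)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(l, v,
                                          levels = c("control", "failure"),
                                          direction = "auto", quiet = TRUE)))
    # pROC picks its direction from group medians, so near-null markers can
    # come out below 0.5; orient both to >= 0.5 before comparing
    expect_equal(roc_analysis(v, l)$auc, max(ref, 1 - ref), tolerance = 1e-12)
  }
})

test_that("the Youden cut-off is globally optimal over observed thresholds", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    v <- round(rnorm(n, 1, 0.4), 1)
    l <- sample(c("failure", "control"), n, replace = TRUE)
    if (length(unique(l)) < 2) next
    r <- roc_analysis(v, l)
    best_j <- r$sensitivity + r$specificity - 100
    for (t in unique(v)) {
      call_pos <- if (r$orientation == "above") v >= t else v <= t
      sens <- 100 * sum(call_pos & l == "failure") / sum(l == "failure")
      spec <- 100 * sum(!call_pos & l == "control") / sum(l == "control")
      expect_lte(sens + spec - 100, best_j + 1e-9)
    }
  }
})

test_that("Kaplan-Meier estimates match hand computation and the ECDF", {
  # no censoring: survival curve is 1 - ECDF at every event time
  set.seed(5)
  t <- sample(1:40, 25, replace = TRUE)
  km <- km_estimate(t, rep(TRUE, 25))
  ecdf_t <- ecdf(t)
  expect_equal(km$surv, 1 - ecdf_t(km$time))
  # hand product-limit on {2, 4+, 6}: S(2) = 2/3, S(6) = 2/3 * 0 = 0
  km <- km_estimate(c(2, 4, 6), c(TRUE, FALSE, TRUE))
  expect_equal(km$surv[km$time == 2], 2 / 3)
  expect_equal(km$surv[km$time == 6], 0)
})

test_that("log-rank splits behave on identical and default cohorts", {
  # label permutation of one sample: statistic exactly 0
  times <- c(3, 5, 8, 12, 20, 30)
  tab <- data.frame(group = "failure",
                    x = rep(c(0, 1), each = 6),
                    pfs_months = rep(times, 2),
                    event = rep(c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE), 2))
  k <- km_logrank(tab, "x", cutoff = 0.5)
  expect_equal(unname(k$chisq), 0)
  # default simulated cohort: control stratum never reaches median survival
  cohort <- simulate_cohort(cohort_spec(seed = 12))
  k <- km_logrank(cohort, "group", cutoff = NULL)
  ctrl <- match("control", k$groups)
  expect_equal(k$events[ctrl], 0)
  expect_equal(k$incidence[ctrl], 0)
  expect_true(is.na(k$median_survival[ctrl]))
  expect_error(km_logrank(cohort, "ADCmean", cutoff = -5),
               class = "ivimprog_input_error")
})

test_that("forward Cox selection reports traces and resists collinearity", {
  tab <- simulate_cohort(cohort_spec(n_failure = 300, n_control = 300,
                                     seed = 31))
  tab <- inject_effect(tab, "Dstar", hazard_ratio = 1.01, seed = 7)
  set.seed(44)
  tab$Dstar_twin <- tab$Dstar + rnorm(nrow(tab), 0, 1)
  res <- cox_forward(tab, c("Dstar", "Dstar_twin"), screen = "cox")
  # near-duplicate covariates: only one of the pair enters
  expect_lte(sum(c("Dstar", "Dstar_twin") %in% res$selected), 1L)
  expect_true(all(res$coefficients$ci_lower <= res$coefficients$hr))
  expect_true(all(res$coefficients$hr <= res$coefficients$ci_upper))
  expect_equal(nrow(res$trace), length(res$selected))
  # no events: classed error
  none <- tab
  none$event <- FALSE
  expect_error(cox_forward(none, "Dstar"), class = "ivimprog_input_error")
})

test_that("the full prognostic table stage produces one row per parameter", {
  cohort <- simulate_cohort(cohort_spec(seed = 19))
  res <- prognosis_tables(cohort)
  params <- cohort_param_names()
  expect_setequal(setdiff(res$comparison$parameter, "n_stage"), params)
  expect_setequal(res$roc$parameter, params)
  expect_true(all(res$roc$auc >= 0.5 & res$roc$auc <= 1))
  expect_equal(sum(res$km$parameter == "Dstar"), 2L)  # two strata rows
})
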