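test_that("accuracy and recall follow the group-percentage definitions", {
  calls <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    call = rep(c("low", "high"), c(10, 2))
  )
  labels <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    label = c(rep("non_recurred", 9), "recurred", "non_recurred", "recurred")
  )
  mr <- accuracy_recall(calls, labels, quiet = TRUE)
  # predicted-low = {9 non-recurred, 1 recurred}; predicted-high = {1, 1};
  # cohort 10 non-recurred / 2 recurred
  expect_equal(mr$low_accuracy, 90)
  expect_equal(mr$low_recall, 90)
  expect_equal(mr$high_accuracy, 50)
  expect_equal(mr$high_recall, 50)
  expect_equal(mr$n, 12L)
  # the four cells reconstruct the percentages
  expect_equal(mr$low_accuracy, 100 * mr$n_low_nonrec / (mr$n_low_nonrec + mr$n_low_rec))
  # order invariance
  perm <- sample.int(12)
  mr2 <- accuracy_recall(calls[perm, ], labels, quiet = TRUE)
  expect_equal(mr, mr2)
})

test_that("empty denominators give NA, never zero", {
  calls <- tibble::tibble(sample_id = c("A", "B"), call = c("low", "low"))
  labels <- tibble::tibble(sample_id = c("A", "B"), label = c("non_recurred", "non_recurred"))
  mr <- accuracy_recall(calls, labels, quiet = TRUE)
  expect_equal(mr$low_accuracy, 100)
  expect_true(is.na(mr$high_accuracy))
  expect_true(is.na(mr$high_recall))
  # unpredicted samples are excluded before counting
  calls2 <- dplyr::add_row(calls, sample_id = "C", call = "unpredicted")
  labels2 <- dplyr::add_row(labels, sample_id = "C", label = "recurred")
  mr2 <- accuracy_recall(calls2, labels2, quiet = TRUE)
  expect_equal(mr2$n, 2L)
  expect_error(
    accuracy_recall(
      tibble::tibble(sample_id = "X", call = "unpredicted"),
      tibble::tibble(sample_id = "X", label = "recurred")
    ),
    class = "nogcss_validation_error"
  )
})

test_that("identical survival in both groups gives chi2 = 0, p = 1", {
  base <- tibble::tibble(dfs_months = c(5, 10, 15, 20), event = c(TRUE, TRUE, FALSE, TRUE))
  rec <- dplyr::bind_rows(
    dplyr::mutate(base, group = "low"),
    dplyr::mutate(base, group = "high")
  )
  km <- km_logrank(rec)
  expect_equal(km$chi2, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  expect_equal(km$n, 8L)
})

# log-rank statistic recomputed from scratch (observed minus expected over
# the risk sets at each distinct event time; hypergeometric variance)
logrank_by_hand <- function(time, event, group) {
  g <- as.integer(group == "high")
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

test_that("the log-rank chi2 matches a from-scratch computation and a permutation oracle", {
  fix <- tibble::tibble(
    dfs_months = c(3, 6, 9, 12, 18, 24),
    event = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    group = c("high", "high", "high", "low", "low", "low")
  )
  km <- km_logrank(fix)
  expect_equal(km$chi2, logrank_by_hand(fix$dfs_months, fix$event, fix$group),
    tolerance = 1e-8
  )
  # permutation oracle: permute group labels, compare the tail probability
  # of the observed statistic with the chi-square p
  withr::local_seed(1)
  perm <- replicate(10000, {
    g <- sample(fix$group)
    logrank_by_hand(fix$dfs_months, fix$event, g)
  })
  p_perm <- mean(perm >= km$chi2 - 1e-12)
  expect_lt(abs(p_perm - km$p), 0.1)
})

test_that("risk-group survival separates at study-like hazards", {
  # n = 200 with 15% recurrence, hazards 0.005 vs 0.02 per month
  detected <- vapply(1:10, function(s) {
    withr::local_seed(300 + s)
    lab <- rep(c("recurred", "non_recurred"), c(30, 170))
    t_ev <- rexp(200, ifelse(lab == "recurred", 0.02, 0.005))
    t_c <- pmin(120, runif(200, 30, 120))
    rec <- tibble::tibble(
      dfs_months = pmin(t_ev, t_c),
      event = t_ev <= t_c,
      group = ifelse(lab == "recurred", "high", "low")
    )
    km_logrank(rec)$p < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.9)
})

test_that("survival input validation and curve export", {
  expect_error(
    km_logrank(tibble::tibble(dfs_months = 1:3, event = TRUE, group = "low")),
    class = "nogcss_validation_error"
  )
  expect_error(
    km_logrank(tibble::tibble(
      dfs_months = c(-1, 2), event = TRUE,
      group = c("low", "high")
    )),
    class = "nogcss_validation_error"
  )
  km <- km_logrank(tibble::tibble(
    dfs_months = c(1, 2, 3, 4), event = c(TRUE, FALSE, TRUE, FALSE),
    group = c("low", "low", "high", "high")
  ))
  td <- tidy(km)
  expect_true(all(c("group", "time", "surv", "n_risk") %in% names(td)))
  expect_true(all(td$surv >= 0 & td$surv <= 1))
  expect_equal(glance(km)$n, 4L)
})

test_that("Cox on a single binary covariate agrees with the log-rank test", {
  withr::local_seed(17)
  n <- 500
  grp <- rep(c("high", "low"), each = n / 2)
  t_ev <- rexp(n, ifelse(grp == "high", 0.02, 0.01))
  rec <- tibble::tibble(
    dfs_months = pmin(t_ev, 100),
    event = t_ev <= 100,
    group = grp,
    arm = as.integer(grp == "high")
  )
  km <- km_logrank(rec)
  cox <- survival::coxph(survival::Surv(dfs_months, event) ~ arm, data = rec)
  # the Cox score test on a binary covariate IS the log-rank statistic
  expect_equal(unname(summary(cox)$sctest["test"]), km$chi2, tolerance = 1e-6)
  # and the likelihood-ratio p agrees asymptotically
  p_lr <- unname(summary(cox)$logtest["pvalue"])
  expect_lt(abs(log(p_lr) - log(km$p)) / abs(log(km$p)), 0.15)
})

test_that("covariate comparison reports per-model p-values alongside the risk grouping", {
  withr::local_seed(23)
  n <- 300
  rec <- tibble::tibble(
    dfs_months = rexp(n, 0.01),
    event = runif(n) < 0.7,
    group = sample(c("low", "high"), n, replace = TRUE),
    age = rnorm(n, 60, 10),
    stage = sample(1:4, n, replace = TRUE),
    nodal = 1 # no variation: must be dropped
  )
  expect_warning(out <- cox_covariates(rec), "no variation")
  expect_setequal(out$model, c("age", "stage", "age+stage", "nog_css_group"))
  expect_true(all(out$converged))
  # covariates independent of survival: no extreme significance expected
  expect_true(all(out$loglik_p[out$model %in% c("age", "stage")] > 1e-4))
  suppressWarnings(expect_error(
    cox_covariates(dplyr::mutate(rec, age = 1, stage = 2), covariates = c("age", "stage")),
    class = "nogcss_validation_error"
  ))
})

test_that("Welch comparisons match the textbook formula to 1e-10", {
  x <- c(2.1, 3.4, 1.9, 5.2, 4.4, 3.3)
  y <- c(4.8, 6.1, 5.5, 7.0, 6.6)
  m <- matrix(c(x, y), nrow = 1, dimnames = list("f", sprintf("S%02d", 1:11)))
  calls <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:11),
    call = rep(c("low", "high"), c(6, 5))
  )
  out <- compare_groups(m, calls)
  se2 <- var(x) / 6 + var(y) / 5
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 6)^2 / 5 + (var(y) / 5)^2 / 4)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(out$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(out$df, df_hand, tolerance = 1e-10)
  expect_equal(out$p_value, p_hand, tolerance = 1e-10)
})

test_that("identical groups give t = 0, p = 1; tiny groups give NA", {
  v <- c(1.2, 3.1, 2.4, 4.4)
  m <- matrix(c(v, v), nrow = 1, dimnames = list("f", sprintf("S%d", 1:8)))
  calls <- tibble::tibble(
    sample_id = sprintf("S%d", 1:8),
    call = rep(c("low", "high"), each = 4)
  )
  out <- compare_groups(m, calls)
  expect_equal(out$t_statistic, 0)
  expect_equal(out$p_value, 1)
  calls1 <- tibble::tibble(sample_id = sprintf("S%d", 1:8), call = c("low", rep("high", 7)))
  expect_true(is.na(compare_groups(m, calls1)$p_value))
})

test_that("a 0.5-SD metagene shift is detected at n = 100 per group", {
  detected <- vapply(1:10, function(s) {
    withr::local_seed(600 + s)
    m <- matrix(c(rnorm(100, 0.5), rnorm(100)),
      nrow = 1,
      dimnames = list("MDSC", sprintf("S%03d", 1:200))
    )
    calls <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:200),
      call = rep(c("high", "low"), each = 100)
    )
    compare_groups(m, calls)$p_value < 0.05
  }, logical(1))
  # closed-form power of the two-sided Welch test at delta = 0.5 is ~0.94
  expect_gte(mean(detected), 0.8)
})

test_that("BH adjustment is off by default and available by flag", {
  withr::local_seed(9)
  m <- matrix(rnorm(40), nrow = 4, dimnames = list(paste0("f", 1:4), paste0("S", 1:10)))
  calls <- tibble::tibble(sample_id = paste0("S", 1:10), call = rep(c("low", "high"), 5))
  expect_false("q_value" %in% names(compare_groups(m, calls)))
  adj <- compare_groups(m, calls, adjust = TRUE)
  expect_true(all(adj$q_value >= adj$p_value - 1e-12))
})
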