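test_that("Fisher exact matches exhaustive fixed-margin enumeration", {
  tab <- matrix(c(10, 10, 3, 31), 2, 2)
  expect_equal(fisher_exact_2x2(tab, "greater"), 0.0010866, tolerance = 1e-4)
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2), "two_sided"), 1)

  set.seed(21)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 8) + 1, 2, 2)
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(fisher_exact_2x2(t2, alt), oracle_fisher(t2, alt),
                   tolerance = 1e-10)
    }
  }
  # one-sided tails share the observed table, so they sum to >= 1
  expect_gte(fisher_exact_2x2(tab, "greater") + fisher_exact_2x2(tab, "less"), 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2), "greater"), "degenerate")
})

test_that("Pearson chi-squared reproduces printed cohort statistics", {
  relapse <- rbind(c(2, 7, 3), c(2, 1, 5))
  res <- chi2_test(relapse)
  expect_equal(res$statistic, 4.375, tolerance = 1e-3)
  expect_identical(res$df, 2L)
  expect_equal(round(res$p_value, 2), 0.11)

  bcl6 <- rbind(c(4, 5, 8), c(0, 3, 0))
  res2 <- chi2_test(bcl6)
  expect_equal(res2$statistic, 5.294, tolerance = 1e-3)
  expect_equal(round(res2$p_value, 2), 0.07)

  # a table equal to its expected counts gives exactly zero signal
  null_tab <- rbind(c(10, 20), c(20, 40))
  res3 <- chi2_test(null_tab)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
  expect_equal(res3$expected, null_tab, ignore_attr = TRUE)
})

test_that("chi-squared equals the 2x2 closed form and is permutation-invariant", {
  set.seed(5)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 10) + 1, 2, 2)
    expect_equal(chi2_test(tab)$statistic, oracle_chi2_2x2(tab), tolerance = 1e-10)
  }
  tab <- matrix(c(3, 9, 5, 2, 8, 4), 2, 3)
  base <- chi2_test(tab)
  expect_equal(chi2_test(tab[2:1, ])$statistic, base$statistic)
  expect_equal(chi2_test(tab[, c(2, 3, 1)])$statistic, base$statistic)
  expect_error(chi2_test(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("spearman_bh matches a hand-rolled rank oracle and handles constants", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  res <- spearman_bh(list(identity = x, target = y), y)
  expect_equal(res$rho[1], oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(res$rho[2], 1)

  distinct <- c(4, 1, 7, 3, 9, 2, 8, 5, 6, 10)
  rev_res <- spearman_bh(list(r = rev(sort(distinct))), sort(distinct))
  expect_equal(rev_res$rho, -1)

  const <- spearman_bh(list(flat = rep(2, 10)), y)
  expect_true(is.na(const$rho))
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  times <- c(3, 1, 7, 2, 9, 5)
  km <- km_estimate(times, rep(1, 6))
  expect_equal(km$surv, 1 - seq_len(6) / 6)
  expect_true(all(diff(km$surv) <= 0))
  # randomized: uncensored KM is the empirical survival at event times
  set.seed(8)
  t2 <- rexp(25)
  km2 <- km_estimate(t2, rep(1, 25))
  emp <- vapply(km2$time, function(u) mean(t2 > u), 0)
  expect_equal(km2$surv, emp, tolerance = 1e-12)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("log-rank matches the per-event hypergeometric summation", {
  # 12-subject two-group fixture with censoring
  times <- c(2, 4, 4, 6, 8, 10, 1, 3, 5, 5, 7, 12)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1, 1)
  group <- rep(c("a", "b"), each = 6)
  res <- logrank_test(times, events, group)
  expect_equal(res$statistic, oracle_logrank(times, events, group), tolerance = 1e-10)
  expect_identical(res$df, 1L)

  # identical groups carry no signal
  t2 <- rep(c(1, 3, 5, 8), 2); e2 <- rep(1, 8); g2 <- rep(c("x", "y"), each = 4)
  res2 <- logrank_test(t2, e2, g2)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1)
  expect_error(logrank_test(t2, rep(0, 8), g2), "events")
})

test_that("log-rank p-values are uniform under the exponential null", {
  set.seed(7)
  ps <- replicate(500, {
    logrank_test(rexp(40), rep(1, 40), rep(c("a", "b"), 20))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("median split applies the documented tie rule and detects effects", {
  expect_identical(unname(median_split(c(1, 2, 3, 4))), c("low", "low", "high", "high"))
  expect_identical(unique(median_split(rep(5, 6))), "low")

  # power check: planted hazard ratio 0.3 on the high group
  set.seed(5)
  score <- rnorm(200)
  grp <- median_split(score)
  t <- rexp(200, rate = 0.05 * ifelse(grp == "high", 0.3, 1))
  expect_lt(logrank_test(t, rep(1, 200), grp)$p_value, 0.05)
})

test_that("association tables cross-tabulate covariates against groups", {
  clin <- clinical_table(data.frame(
    sample_id = paste0("S", 1:12),
    os_time = 1:12, os_event = rep(c(0, 1), 6),
    rfs_time = 1:12, rfs_event = rep(c(1, 0), 6),
    sex = rep(c("M", "F"), each = 6)))
  groups <- stats::setNames(rep(c("g1", "g2"), 6), paste0("S", 1:12))
  res <- association_table(clin, groups)
  expect_identical(res$covariate, "sex")
  tab <- table(clin$sex, groups[clin$sample_id])
  expect_equal(res$p_value, chi2_test(unclass(as.matrix(tab)))$p_value)
})
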