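test_that("paired comparison: gating, constant shifts and degeneracy", {
  set.seed(1)
  rest <- stats::rnorm(12, 66, 9)
  # constant positive shift: infinite paired-t evidence
  res <- paired_compare(rest, rest + 10)
  expect_true(res$degenerate)
  expect_identical(res$test_used, "paired-t")
  expect_lt(res$p_value, 0.001)
  # identical vectors: no p-value at all
  res0 <- paired_compare(rest, rest)
  expect_true(res0$degenerate)
  expect_true(is.na(res0$p_value))
  # evenly spread differences around a large shift: regular paired-t route
  res1 <- paired_compare(rest, rest + 10 + rep(c(-2, -1, 0, 1, 2), 3)[1:12])
  expect_identical(res1$test_used, "paired-t")
  expect_lt(res1$p_value, 0.001)
  expect_gte(res1$normality_p, 0.05)
  # heavy-tailed differences fall through to Wilcoxon
  d <- c(rep(0.01, 11), 40)
  res2 <- paired_compare(rest, rest + d)
  expect_identical(res2$test_used, "wilcoxon")
  expect_error(paired_compare(1:2, 2:3), "n >= 3")
})

test_that("paired comparison holds its nominal type-I error", {
  set.seed(2024)
  reps <- 2000
  rej <- logical(reps)
  wil <- 0L
  for (i in seq_len(reps)) {
    rest <- stats::rnorm(12)
    stress <- rest + stats::rnorm(12)   # symmetric null differences
    r <- paired_compare(rest, stress)
    rej[i] <- r$p_value < 0.05
    wil <- wil + (r$test_used == "wilcoxon")
  }
  expect_gt(mean(rej), 0.04)
  expect_lt(mean(rej), 0.06)
  expect_gt(wil, 0)   # the gate sometimes routes to Wilcoxon under the null
})

test_that("region comparison: gating, sensitivity and degeneracy", {
  set.seed(3)
  grp <- list(AAo = stats::rnorm(12), AoA = stats::rnorm(12),
              DAo = stats::rnorm(12) + 5)
  r <- region_compare(grp)
  expect_identical(r$method, "anova-tukey")
  expect_lt(r$omnibus_p, 1e-6)
  hit <- r$pairwise$group1 == "DAo" | r$pairwise$group2 == "DAo"
  expect_true(all(r$pairwise$p_adj[hit] < 0.001))
  expect_gt(r$pairwise$p_adj[!hit], 0.05)
  # skewed data route to Kruskal-Wallis + Dunn
  grp2 <- lapply(grp, function(x) exp(2 * x))
  r2 <- region_compare(grp2)
  expect_identical(r2$method, "kruskal-dunn")
  hit2 <- r2$pairwise$group1 == "DAo" | r2$pairwise$group2 == "DAo"
  expect_true(all(r2$pairwise$p_adj[hit2] < 0.01))
  # identical groups: nothing significant
  same <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  r3 <- region_compare(same)
  expect_true(r3$degenerate)
  expect_true(all(r3$pairwise$p_adj == 1))
  expect_error(region_compare(list(a = 1:2, b = 1:5)), "n >= 3")
})

test_that("region comparison holds its familywise type-I error", {
  set.seed(99)
  reps <- 2000
  any_sig <- logical(reps)
  for (i in seq_len(reps)) {
    grp <- list(a = stats::rnorm(12), b = stats::rnorm(12),
                c = stats::rnorm(12))
    r <- region_compare(grp)
    any_sig[i] <- any(r$pairwise$p_adj < 0.05)
  }
  expect_gt(mean(any_sig), 0.04)
  expect_lt(mean(any_sig), 0.06)
})

test_that("fold changes reproduce printed one-decimal ratios", {
  expect_identical(fold_change(2.86, 8.04), 2.8)
  expect_identical(fold_change(1.16, 3.41), 2.9)
  expect_identical(fold_change(1.47, 4.09), 2.8)
  expect_identical(fold_change(5, 5), 1)
  expect_error(fold_change(0, 3), "positive")
  # round-trip products stay within one rounding step of 1
  for (r in seq(0.5, 2, by = 0.01)) {
    prod <- fold_change(1, r) * fold_change(r, 1)
    expect_lt(abs(prod - 1), 0.1 + 1e-9)
  }
})

test_that("linear fit matches closed forms and the null expectation", {
  x <- 1:10
  f <- linear_fit(x, 2 * x)
  expect_equal(f$r_squared, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_error(linear_fit(rep(1, 5), 1:5), "constant")
  expect_error(linear_fit(1:2, 1:2), "n >= 3")
  # E[R^2] = 1/(n-1) under independence
  set.seed(4)
  n <- 24; reps <- 2000
  r2 <- replicate(reps, linear_fit(stats::rnorm(n),
                                   stats::rnorm(n))$r_squared)
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.01)
})

test_that("regression recovers a CO-driven TKE relationship", {
  # peak TKE_total proportional to CO with 10% multiplicative noise
  set.seed(5)
  ch <- make_cohort(12, seed = 5)
  co <- ch$truth$co
  tke <- 0.55 * co * (1 + stats::rnorm(length(co), 0, 0.10))
  fit <- linear_fit(co, tke)
  expect_gt(fit$r_squared, 0.8)
  expect_lt(fit$p_value, 1e-6)
  # R^2 degrades monotonically (on average) with the noise level
  mean_r2 <- vapply(c(0.02, 0.1, 0.3, 0.6), function(s) {
    mean(replicate(200, {
      y <- 0.55 * co * (1 + stats::rnorm(length(co), 0, s))
      linear_fit(co, y)$r_squared
    }))
  }, numeric(1))
  expect_true(all(diff(mean_r2) < 0))
})

test_that("ICC(A,k) reproduces an independent reference computation", {
  base <- c(171.4, 316.7, 121.9, 200.9, 135.3, 253.5, 176.3, 334.2)
  r2 <- base + c(3.1, -8.2, 5.4, -2.7, 1.9, 6.3, -4.4, 2.2)
  res <- icc_agreement(cbind(base, r2))
  # frozen from pingouin::intraclass_corr (type ICC2k) on the same matrix
  expect_equal(res$icc, 0.9990964701453061, tolerance = 1e-12)
  m <- matrix(c(9, 2, 5, 6, 1, 3, 8, 4, 6, 7, 1, 2, 10, 5, 6, 6, 2, 4),
              6, 3, byrow = TRUE)
  res2 <- icc_agreement(m)
  expect_equal(res2$icc, 0.4634146341463414, tolerance = 1e-12)
  # pingouin prints its CI rounded to 2 decimals: [-0.03, 0.88]
  expect_identical(round(res2$lower, 2), -0.03)
  expect_identical(round(res2$upper, 2), 0.88)
})

test_that("ICC behaviour: perfect agreement, noise, shift invariance, bound", {
  set.seed(6)
  x <- stats::rnorm(10, 100, 20)
  expect_equal(icc_agreement(cbind(x, x))$icc, 1)
  res_deg <- icc_agreement(matrix(5, 6, 2))
  expect_true(res_deg$degenerate)
  expect_identical(res_deg$icc, 1)
  # independent "ratings" give low (possibly negative) agreement
  noisy <- icc_agreement(cbind(x, stats::rnorm(10, 100, 20)))
  expect_lt(noisy$icc, 0.6)
  # adding a common constant to all ratings changes nothing
  m <- cbind(x, x + stats::rnorm(10, 0, 5))
  expect_equal(icc_agreement(m)$icc, icc_agreement(m + 50)$icc,
               tolerance = 1e-12)
  for (i in 1:10) {
    mm <- matrix(stats::rnorm(14), 7, 2)
    expect_lte(icc_agreement(mm)$icc, 1)
  }
  expect_error(icc_agreement(matrix(1:8, 4, 2)), "5 subjects")
})

test_that("cardiac output arithmetic", {
  expect_identical(derived_co(66, 88), 5.8)
  expect_identical(derived_co(108, 102), 11)
  expect_identical(derived_co(60, 1000), 60)
  expect_equal(derived_co(66, 88, digits = NULL), 5.808)
  expect_error(derived_co(-1, 88), "hr > 0")
})

test_that("printed-table arithmetic report recomputes every target", {
  rep <- reproduce_table_arithmetic()
  expect_setequal(rep$id, c("t1", "t2", "t3", "t4", "t5", "t6", "aoa_fold"))
  expect_true(all(rep$pass[rep$asserted]))
  aoa <- rep[rep$id == "aoa_fold", ]
  expect_false(aoa$asserted)
  expect_identical(aoa$computed, 2.4)   # printed 2.5 is not recoverable
  tabs <- reference_tables()
  expect_identical(tabs$peaks$rest_mean[tabs$peaks$parameter == "peak_tke_total" &
                                          tabs$peaks$region == "TAo"], 2.86)
  broken <- tabs
  broken$peaks <- broken$peaks[broken$peaks$region != "TAo", ]
  expect_error(reproduce_table_arithmetic(broken), "missing fixture")
})
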