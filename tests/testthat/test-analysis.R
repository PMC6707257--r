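test_that("per-capita killing is the exact quotient", {
  expect_equal(per_capita_killing(0, 5), 0)
  expect_equal(per_capita_killing(3000, 250), 12)
  expect_equal(per_capita_killing(10, 4), 2.5)
  expect_true(is.na(per_capita_killing(3, 0)))
  expect_error(per_capita_killing(-1, 5), ">= 0")
  # homogeneity: scaling both counts leaves k_ctl unchanged
  for (f in c(2, 10, 0.5)) {
    expect_equal(per_capita_killing(30 * f, 7 * f), per_capita_killing(30, 7))
  }
})

test_that("kill repartition pools integer ledgers into a unit histogram", {
  r <- kill_repartition(fake_run(c(0, 3)))
  expect_equal(unname(r$histogram), c(0.5, 0, 0, 0.5))
  expect_equal(names(r$histogram), c("0", "1", "2", "3"))
  r0 <- kill_repartition(fake_run(c(0, 0, 0)))
  expect_equal(unname(r0$histogram), 1)
  # pooled mass is 1 on random ledgers, fraction > 5 and max are consistent
  set.seed(8)
  for (i in 1:5) {
    runs <- lapply(1:3, function(j) fake_run(rpois(20, 3)))
    rep <- kill_repartition(runs)
    expect_equal(sum(rep$histogram), 1, tolerance = 1e-9)
    kills <- unlist(lapply(runs, function(x) x$ledger$kills_int))
    expect_equal(rep$fraction_gt5, mean(kills > 5))
    expect_equal(rep$max_kills, max(kills))
  }
  expect_error(kill_repartition(fake_run(1), use = "kills_frac"),
               "integer-credit")
})

test_that("temporal per-capita tracks kills over the CTL present", {
  ser <- data.frame(time_h = c(0, 1, 2, 3),
                    cum_deaths = c(0, 4, 10, 10),
                    n_ctl = c(5, 5, 5, 10)) # cohort arrives at t = 3
  out <- temporal_per_capita(fake_run(0, series = ser))
  expect_equal(out$k_ctl, c(0, 0.8, 2, 1))
  # denominator step drops k by the old/new CTL ratio
  expect_equal(out$k_ctl[4] / out$k_ctl[3], 5 / 10)
  # all-zero kills give an all-zero series
  ser0 <- data.frame(time_h = 0:2, cum_deaths = 0, n_ctl = 3)
  expect_equal(temporal_per_capita(fake_run(0, series = ser0))$k_ctl,
               rep(0, 3))
})

test_that("rank-sum test: exact enumeration, ties, symmetry", {
  # complete separation of 3 vs 3: one-sided 1/20, two-sided 0.1
  out <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$p_value, 0.1)
  expect_equal(out$method, "exact")
  # identical samples: p = 1
  expect_equal(suppressWarnings(rank_sum_test(c(2, 2, 2), c(2, 2, 2)))$p_value, 1)
  a <- c(1, 5, 7); b <- c(2, 3, 9, 11)
  expect_equal(rank_sum_test(a, b)$p_value, rank_sum_test(b, a)$p_value)
  # exact branch agrees with the reference implementation
  expect_equal(rank_sum_test(a, b)$p_value,
               stats::wilcox.test(a, b)$p.value)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact and normal branches agree on moderate samples", {
  set.seed(9)
  for (i in 1:5) {
    a <- round(runif(5, 0, 100), 3)
    b <- round(runif(5, 20, 120), 3)
    pe <- rank_sum_test(a, b, exact_max = 12)$p_value
    pn <- rank_sum_test(a, b, exact_max = 0)$p_value
    expect_lt(abs(pe - pn), 0.05)
    # and the exact branch matches wilcox.test exactly
    expect_equal(pe, stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})
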