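test_that("killing assay reports per-ratio statistics", {
  p <- small_params(n_targets = 40, duration_h = 2, seed = 2)
  des <- assay_design(et_ratios = 0.5, duration_h = 2, n_runs = 1,
                      line = "conventional")
  cv <- killing_assay(des, p, master_seed = 5, keep_runs = TRUE)
  expect_s3_class(cv, "killing_curve")
  expect_equal(nrow(cv), 1)
  r <- attr(cv, "runs")[[1]][[1]]
  expect_equal(cv$pct_killed_mean, 100 * r$cum_deaths / r$initial_targets)
  expect_equal(cv$pct_killed_sd, 0)

  # a 0-CTL control well kills nothing; per-capita is missing
  des0 <- assay_design(et_ratios = 0, duration_h = 1, n_runs = 2,
                       line = "conventional")
  cv0 <- killing_assay(des0, p, master_seed = 5)
  expect_equal(cv0$pct_killed_mean, 0)
  expect_true(is.na(cv0$per_capita_mean))

  # rows come back sorted by ratio
  des2 <- assay_design(et_ratios = c(1, 0.2), duration_h = 1, n_runs = 1,
                       line = "conventional")
  cv2 <- killing_assay(des2, p, master_seed = 5)
  expect_equal(cv2$et_ratio, c(0.2, 1))
})

test_that("optimal ratio search returns the smallest controlling ratio", {
  # conventional targets over a short window: high ratios control growth
  p <- small_params("conventional", n_targets = 40, duration_h = 6, seed = 3)
  sw <- optimal_ratio_search(p, ratio_min = 0.5, ratio_max = 2.5, step = 1,
                             duration_h = 6, n_runs = 2, master_seed = 9)
  expect_equal(nrow(sw$table), 3) # every grid ratio evaluated
  if (sw$controlled) {
    i <- match(sw$optimal_ratio, sw$table$et_ratio)
    expect_true(sw$table$mean_final[i] <= 40)
    if (i > 1) expect_true(all(sw$table$mean_final[seq_len(i - 1)] > 40))
  } else {
    expect_true(all(sw$table$mean_final > 40))
  }
  expect_error(optimal_ratio_search(p, ratio_min = 1, ratio_max = 0.5),
               "ratio_min")
})

test_that("long-term trajectories behave at the extremes", {
  p <- small_params(n_targets = 25, seed = 4)
  # no CTL: mean trajectory monotone non-decreasing
  lt0 <- long_term_experiment(p, et_ratios = 0, duration_h = 30, n_runs = 3,
                              master_seed = 11)
  expect_true(all(diff(lt0$mean_live) >= 0))
  # overwhelming ratio: reaches zero and stays (absorbing)
  p2 <- small_params("conventional", n_targets = 25, seed = 4)
  lt <- long_term_experiment(p2, et_ratios = 10, duration_h = 30, n_runs = 3,
                             master_seed = 12)
  expect_equal(lt$mean_live[nrow(lt)], 0)
  z <- which(lt$mean_live == 0)[1]
  expect_true(all(lt$mean_live[z:nrow(lt)] == 0))
})

test_that("sequential comparison enforces equal totals and runs arms", {
  p <- small_params(n_targets = 20, seed = 5)
  expect_error(sequential_addition_experiment(
    p, list(cohort_schedule(c(0, 4), c(5, 5))), bolus_total = 12,
    duration_h = 2, n_runs = 2), "10.*12|12.*10")
  cmp <- sequential_addition_experiment(
    p, list(cohort_schedule(0, 10)), bolus_total = 10,
    duration_h = 2, n_runs = 3, master_seed = 8)
  expect_equal(nrow(cmp$arms), 2)
  expect_equal(cmp$arms$n_runs, c(3, 3))
  expect_true(cmp$tests$p_value >= 0 && cmp$tests$p_value <= 1)
  expect_error(cohort_schedule(c(4, 0), c(5, 5)), "non-decreasing")
})
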