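test_that("growth fitting recovers exact and simulated doubling times", {
  # exact doubling every 24 h
  g <- growth_series(c(0, 24, 48, 72), c(1e5, 2e5, 4e5, 8e5))
  f <- fit_growth(g)
  expect_equal(f$doubling_time_h, 24)
  expect_equal(f$r_squared, 1)
  expect_equal(f$cycle$g1s_mean_h, 18)  # 0.75 split
  expect_equal(f$cycle$g2m_mean_h, 6)

  # flat series: Inf sentinel with a warning
  gf <- growth_series(c(0, 24, 48), c(100, 100, 100))
  expect_warning(ff <- fit_growth(gf), "flat")
  expect_equal(ff$doubling_time_h, Inf)
  expect_true(ff$flat)

  expect_warning(fit_growth(growth_series(c(0, 24, 48, 72),
                                          c(100, 140, 120, 160))),
                 "decreasing")
  expect_error(growth_series(c(0, 24), c(10, -2)), "> 0")
  expect_error(fit_growth(growth_series(c(0, 24), c(10, 20))), "3 obs")

  # round trip: refit a simulated 0-CTL culture with known Tc = 20 h
  # (72 h horizon averages out the asynchronous-seed transient)
  p <- default_params("conventional", initial_targets = 80, initial_ctl = 0,
                      duration_h = 72, record_every_min = 120)
  hrs <- c(0, 24, 48, 72)
  counts <- matrix(0, nrow = 3, ncol = length(hrs))
  for (j in 1:3) {
    p$seed <- j
    r <- run_simulation(p, record_events = FALSE)
    idx <- vapply(hrs, function(h)
      which.min(abs(r$series$time_h - h)), integer(1))
    counts[j, ] <- r$series$live_targets[idx]
  }
  fit <- fit_growth(growth_series(hrs, colMeans(counts)))
  expect_equal(fit$doubling_time_h, 20, tolerance = 0.05)
})

test_that("mse distance is a valid squared-error mean", {
  ref <- as_killing_reference(data.frame(
    line = "melanoma", et_ratio = c(0.1, 0.5, 1),
    cytotoxicity = c(10, 30, 60)))
  expect_equal(mse_distance(ref, ref), 0)
  shifted <- ref
  shifted$cytotoxicity <- ref$cytotoxicity + 2
  expect_equal(mse_distance(shifted, ref), 4)
  # quadratic scaling under a uniform offset
  shifted$cytotoxicity <- ref$cytotoxicity + 6
  expect_equal(mse_distance(shifted, ref), 36)
  # hand-computed on a 3-cell toy table
  other <- ref
  other$cytotoxicity <- c(12, 27, 61)
  expect_equal(mse_distance(other, ref), mean(c(4, 9, 1)))
  expect_equal(mse_distance(other, ref), mse_distance(ref, other))
  bad <- ref[1:2, ]
  expect_error(mse_distance(bad, ref), "grid")
})

test_that("fold-over-basal references convert to percent killed", {
  df <- data.frame(line = "melanoma", et_ratio = c(0.1, 1),
                   cytotoxicity = c(2, 8),
                   measure_kind = "fold_over_basal",
                   basal_fraction = 0.05)
  ref <- as_killing_reference(df)
  expect_equal(ref$cytotoxicity, c(10, 40))
  expect_warning(as_killing_reference(df[, 1:4]), "basal_fraction")
})

test_that("grid search scores every couple and breaks ties deterministically", {
  p <- small_params("conventional", n_targets = 30, seed = 7)
  ref <- as_killing_reference(data.frame(
    line = "conventional", et_ratio = 0.5, cytotoxicity = 30))
  gr <- calibration_grid(rd_values = c(50, 100), pd_values = c(0.001, 0.003),
                         runs_per_point = 1)
  out <- grid_search_rd_pd(gr, ref, p, et_ratios = 0.5, duration_h = 2,
                           master_seed = 3)
  expect_equal(nrow(out$scores), 4) # |rd| x |pd| entries
  expect_true(all(is.finite(out$scores$score)))
  i <- which.min(out$scores$score)
  expect_equal(out$best$score, out$scores$score[i])
  # 1x1 grid: that point is best trivially
  g1 <- calibration_grid(rd_values = 100, pd_values = 0.001,
                         runs_per_point = 1)
  o1 <- grid_search_rd_pd(g1, ref, p, et_ratios = 0.5, duration_h = 2,
                          master_seed = 3)
  expect_equal(o1$best$rd, 100)
  expect_equal(o1$best$pd, 0.001)
})
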