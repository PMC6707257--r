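test_that("initialize_well packs cells centrally without overlap", {
  p <- default_params("melanoma", initial_targets = 10, initial_ctl = 0)
  set.seed(1)
  w <- initialize_well(p)
  expect_equal(nrow(w$targets), 10)
  # relaxed below the contact tolerance
  expect_lt(ctlsim:::cpp_max_overlap(ctlsim:::.well_to_cpp(w)), 0.05)
  # all near the center (packing disc + relaxation slack)
  disc <- sqrt(1.3 * sum(w$targets$radius^2))
  rr <- sqrt(w$targets$x^2 + w$targets$y^2)
  expect_true(all(rr < disc + 4 * max(w$targets$radius)))

  # E/T ratio 1 creates exactly one CTL per target
  p2 <- default_params("melanoma", initial_targets = 100, et_ratio = 1)
  w2 <- initialize_well(p2, seed = 2)
  expect_equal(nrow(w2$ctls), 100)
  # determinism
  w3 <- initialize_well(p2, seed = 2)
  expect_identical(w2, w3)
  # infeasible packing is a configuration error
  pbad <- default_params("melanoma", initial_targets = 5,
                         mechanics = mechanics_params(well_radius_um = 20))
  expect_error(initialize_well(pbad), "fit")
})

test_that("runs are reproducible and conserve populations", {
  p <- small_params(n_targets = 50, et_ratio = 0.5, duration_h = 3, seed = 11)
  r1 <- run_simulation(p)
  r2 <- run_simulation(p)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$ledger, r2$ledger)
  expect_identical(r1$events, r2$events)

  s <- r1$series
  expect_true(all(s$live_targets ==
                    r1$initial_targets + s$cum_divisions - s$cum_deaths))
  expect_true(all(s$n_search + s$n_attack + s$n_disabled == s$n_ctl))
  expect_true(all(s$n_ctl == 25))

  # kill-credit conservation: both ledgers sum exactly to the deaths
  expect_equal(sum(r1$ledger$kills_frac), r1$cum_deaths)
  expect_equal(sum(r1$ledger$kills_int), r1$cum_deaths)

  # DISABLED is absorbing: one DISABLE event per CTL at most, count matches
  dis <- r1$events[r1$events$type == "DISABLE", ]
  expect_false(any(duplicated(dis$id1)))
  expect_equal(nrow(dis), s$n_disabled[nrow(s)])
})

test_that("duration 0 returns the initialized snapshot", {
  p <- small_params(n_targets = 10, duration_h = 0)
  r <- run_simulation(p)
  expect_equal(nrow(r$series), 1)
  expect_equal(r$series$live_targets, 10)
  expect_equal(r$series$time_h, 0)
})

test_that("cohort additions enter in SEARCH mode at the scheduled step", {
  p <- small_params(n_targets = 30, et_ratio = 0, duration_h = 2, seed = 4)
  set.seed(4)
  w <- initialize_well(p)
  w20 <- add_ctl_cohort(w, 20, p)
  expect_equal(nrow(w20$ctls), 20)
  expect_true(all(w20$ctls$mode == "SEARCH"))
  expect_equal(nrow(w20$targets), 30)
  expect_error(add_ctl_cohort(w, 0, p), "> 0")
  set.seed(4); wa <- add_ctl_cohort(w, 20, p)
  set.seed(4); wb <- add_ctl_cohort(w, 20, p)
  expect_identical(wa, wb)

  # scheduled addition inside a run steps the CTL series up
  p2 <- small_params(n_targets = 30, et_ratio = 0, duration_h = 2, seed = 5)
  p2$cohort_schedule <- data.frame(time_h = 1, n = 15)
  r <- run_simulation(p2)
  # the cohort lands at the first step whose clock reaches 1 h, so rows up to
  # and including t = 1 h show 0 CTL and later rows show the cohort
  expect_true(all(r$series$n_ctl[r$series$time_h <= 1] == 0))
  expect_true(all(r$series$n_ctl[r$series$time_h > 1] == 15))
})

test_that("population cap truncates the run with an escaped flag", {
  p <- small_params(n_targets = 40, duration_h = 60, max_pop = 60, seed = 6)
  r <- run_simulation(p, record_events = FALSE)
  expect_true(r$escaped)
  expect_lt(r$series$time_h[nrow(r$series)], 60)
  expect_gt(r$series$live_targets[nrow(r$series)], 60)
})

test_that("kill counts are robust to halving the time step", {
  # P_d is expressed per reference step and rescaled through the hazard
  # identity, so halving dt must leave 6 h kill statistics unchanged up to
  # Monte-Carlo error (spec tolerance 5% on the mean over 20 runs)
  base <- default_params("conventional", initial_targets = 120, et_ratio = 0.5,
                         duration_h = 6, record_every_min = 60)
  kills <- function(dt, seeds) vapply(seeds, function(s) {
    p <- base
    p$mechanics <- mechanics_params(dt_min = dt)
    p$seed <- s
    run_simulation(p, record_events = FALSE)$cum_deaths
  }, numeric(1))
  k1 <- kills(0.5, 1:20)
  k2 <- kills(0.25, 21:40)
  expect_lt(abs(mean(k1) - mean(k2)) / mean(k1), 0.05)
})

test_that("R single-agent rules and the C++ loop agree on a scripted duel", {
  # 1 pinned CTL vs 1 target: step the R reference ops by hand and compare
  # the death step with the engine's
  kp <- killing_params(survival_h = 2, pd = 0)
  cell <- target_cells(1L, 0, 0, phase_remaining = 1e6, g1s_dur = 1e6,
                       g2m_dur = 300, survival_remaining = 120)
  att <- ctl_cells(2L, 13, 0, mode = "ATTACK", bonded_target = 1L)
  steps_r <- 0
  repeat {
    steps_r <- steps_r + 1
    up <- update_target(cell, att, kp, 0.5)
    cell <- up$cell
    if (cell$dead) break
  }
  p <- pinned_params(survival_min = 120, duration_h = 4)
  r <- run_simulation(p, world = pinned_world(1, survival_min = 120))
  death_step <- r$events$time_h[r$events$type == "DEATH"] * 60 / 0.5
  expect_equal(death_step, steps_r)
})
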