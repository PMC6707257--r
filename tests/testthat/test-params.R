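test_that("parameter constructors validate their invariants", {
  expect_error(mechanics_params(spring_stiffness = -1), "spring_stiffness")
  expect_error(mechanics_params(diffusion_coefficient = -1), "diffusion")
  # stability guard: large dt or large D must be rejected at construction
  expect_error(mechanics_params(diffusion_coefficient = 40, dt_min = 0.5),
               "stability")
  expect_error(mechanics_params(dt_min = 2, spring_stiffness = 0.3),
               "stability")
  expect_error(cycle_phase_params(-1, 0, 1, 0), "means")
  expect_error(killing_params(pd = 1.5), "pd")
  expect_error(killing_params(survival_h = 0), "survival")
  expect_error(simulation_params(duration_h = -1), "duration")
  expect_error(simulation_params(cohort_schedule =
                                   data.frame(time_h = 99, n = 5),
                                 duration_h = 18), "within")
})

test_that("P_d hazard rescaling is step-size invariant", {
  k <- killing_params(pd = 0.01, pd_ref_dt_min = 0.5)
  p_ref <- ctlsim:::.pd_step(k, 0.5)
  expect_equal(p_ref, 0.01)
  p_half <- ctlsim:::.pd_step(k, 0.25)
  # two half-steps must compound to one reference step hazard
  expect_equal(1 - (1 - p_half)^2, 0.01)
  # rescaling to a longer step
  expect_equal(ctlsim:::.pd_step(k, 1), 1 - (1 - 0.01)^2)
})

test_that("et_ratio derives the CTL count", {
  p <- simulation_params(initial_targets = 100, et_ratio = 1)
  expect_identical(p$initial_ctl, 100L)
  p <- simulation_params(initial_targets = 200, et_ratio = 0.25)
  expect_identical(p$initial_ctl, 50L)
})

test_that("derived seeds stay within 32-bit integer range", {
  s <- vapply(1:200, function(i) derive_seed(2^30, i), integer(1))
  expect_true(all(s > 0 & s < 2^31))
  expect_false(any(duplicated(s)))
})
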