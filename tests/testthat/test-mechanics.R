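test_that("brownian displacement has the closed-form moments", {
  set.seed(1)
  # D = 0: no motion
  expect_true(all(brownian_displacement(0, 0.5, 100) == 0))
  # per-axis variance 2 D dt, checked empirically at D = 1, dt = 0.5
  d <- brownian_displacement(1, 0.5, 1e4)
  expect_equal(var(d[, 1]), 1.0, tolerance = 0.05)
  expect_equal(var(d[, 2]), 1.0, tolerance = 0.05)
  # zero mean within 3 standard errors
  se <- sqrt(1.0 / 1e4)
  expect_lt(abs(mean(d[, 1])), 3 * se)
  expect_lt(abs(mean(d[, 2])), 3 * se)
  expect_error(brownian_displacement(-1, 0.5), ">= 0")
  expect_error(brownian_displacement(1, 0), "> 0")
})

test_that("mechanics step is the identity without forces or noise", {
  p <- pinned_params()
  w <- make_well(target_cells(1L, 10, -20), ctl_cells(2L, 200, 150))
  w2 <- step_mechanics(w, p)
  expect_equal(w2$targets$x, w$targets$x)
  expect_equal(w2$ctls[c("x", "y")], w$ctls[c("x", "y")])
  # bonded pair exactly at rest length stays put
  wb <- make_well(target_cells(c(1L, 2L), c(0, 16), c(0, 0)),
                  bonds = data.frame(a = 1L, b = 2L, rest_length = 16))
  wb2 <- step_mechanics(wb, p)
  expect_equal(wb2$targets$x, c(0, 16))
})

test_that("a stretched bond relaxes monotonically to rest length", {
  p <- pinned_params()
  rest <- 16
  w <- make_well(target_cells(c(1L, 2L), c(0, rest * 1.2), c(0, 0)),
                 bonds = data.frame(a = 1L, b = 2L, rest_length = rest))
  # independent fine-step reference: overdamped two-body spring has
  # gap(t) = gap0 * exp(-2 k t / gamma); integrate with dt/100
  m <- p$mechanics
  gap0 <- 0.2 * rest
  gap_ref <- gap0
  fine <- m$dt_min / 100
  err <- numeric(40)
  dist <- rest * 1.2
  for (s in 1:40) {
    w <- step_mechanics(w, p)
    d2 <- abs(diff(w$targets$x))
    expect_lt(d2, dist + 1e-12) # monotone decrease of the error
    dist <- d2
    for (i in 1:100)
      gap_ref <- gap_ref - fine * 2 * m$spring_stiffness / m$damping_coefficient * gap_ref
    err[s] <- abs((d2 - rest) - gap_ref)
  }
  expect_lt(abs(dist - rest), 0.01 * rest)       # converged
  expect_lt(max(err), 0.02 * rest)               # tracks the reference integrator
})

test_that("neighbors_within and detect_contacts match brute-force oracles", {
  for (seed in 1:3) {
    w <- random_world(60, 40, extent = 120, seed = seed)
    for (radius in c(0, 10, 35, 400)) {
      q <- c(5, -7)
      expect_identical(neighbors_within(w, q, radius),
                       brute_neighbors(w, q, radius))
    }
    got <- detect_contacts(w)
    want <- brute_contacts(w)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
  }
  # radius 0 only matches an agent exactly at the query point
  w <- make_well(target_cells(c(1L, 2L), c(0, 5), c(0, 0)))
  expect_identical(neighbors_within(w, c(0, 0), 0), 1L)
  # empty world
  expect_identical(neighbors_within(make_well(), c(0, 0), 10), integer(0))
  # contact boundary cases
  w2 <- make_well(target_cells(c(1L, 2L), c(0, 16), c(0, 0)))
  expect_equal(nrow(detect_contacts(w2)), 1) # exactly touching
  w3 <- make_well(target_cells(c(1L, 2L), c(0, 20), c(0, 0)))
  expect_equal(nrow(detect_contacts(w3)), 0) # beyond tolerance
})

test_that("mechanics conserves agents and keeps them inside the well", {
  p <- small_params()
  p$mechanics <- mechanics_params(well_radius_um = 100)
  set.seed(9)
  w <- initialize_well(default_params("melanoma", initial_targets = 30,
                                      initial_ctl = 20,
                                      mechanics = p$mechanics))
  for (i in 1:20) w <- step_mechanics(w, p)
  expect_equal(nrow(w$targets), 30)
  expect_equal(nrow(w$ctls), 20)
  rr <- sqrt(c(w$targets$x, w$ctls$x)^2 + c(w$targets$y, w$ctls$y)^2)
  lim <- 100 - c(w$targets$radius, w$ctls$radius)
  expect_true(all(rr <= lim + 1e-9))
})
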