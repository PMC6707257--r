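test_that("phase durations follow the truncated normal law", {
  set.seed(2)
  # degenerate sd: exact means
  d0 <- draw_phase_durations(cycle_phase_params(10, 0, 4, 0), 5)
  expect_equal(d0$g1s_h, rep(10, 5))
  expect_equal(d0$g2m_h, rep(4, 5))
  # CLT check of the sample mean
  d <- draw_phase_durations(cycle_phase_params(10, 1, 4, 0.5), 1e4)
  expect_lt(abs(mean(d$g1s_h) - 10), 3 * 1 / sqrt(1e4))
  # heavy truncation still yields strictly positive draws
  dt <- draw_phase_durations(cycle_phase_params(1, 5, 1, 5), 1e4)
  expect_true(all(dt$g1s_h > 0) && all(dt$g2m_h > 0))
})

test_that("target state machine follows the defense/death rules", {
  kp <- killing_params(survival_h = 5, pd = 0)
  cell <- target_cells(1L, 0, 0, phase = "G1S", phase_remaining = 100,
                       g1s_dur = 100, g2m_dur = 40, survival_remaining = 300)
  # cycling with no contact: timer reduced by dt only
  up <- update_target(cell, NULL, kp, 0.5)
  expect_equal(up$cell$phase_remaining, 99.5)
  expect_equal(up$cell$phase, "G1S")
  expect_length(up$events, 0)
  expect_error(update_target(cell, NULL, kp, 0), "dt")

  # death after exactly S / k of contact, k = 1, 2, 3 (closed form S/k
  # checked against step-by-step iteration of the update rule)
  for (k in 1:3) {
    attackers <- ctl_cells(10 + seq_len(k), 0, 0, mode = "ATTACK",
                           bonded_target = 1L)
    c2 <- cell
    steps <- 0
    repeat {
      steps <- steps + 1
      up <- update_target(c2, attackers, kp, 0.5)
      c2 <- up$cell
      if (c2$dead) break
    }
    expect_equal(steps, ceiling(300 / k / 0.5))
    expect_equal(up$events[[1]]$type, "DEATH")
    expect_equal(c2$survival_remaining, 0)
  }

  # defense freezes the cycle timer, escape reverts and keeps depletion
  attackers <- ctl_cells(10L, 0, 0, mode = "ATTACK", bonded_target = 1L)
  c2 <- update_target(cell, attackers, kp, 0.5)$cell
  expect_equal(c2$phase, "DEFENSE")
  expect_equal(c2$stored_phase, "G1S")
  expect_equal(c2$phase_remaining, 100) # frozen
  expect_equal(c2$survival_remaining, 299.5)
  c3 <- update_target(c2, NULL, kp, 0.5)$cell
  expect_equal(c3$phase, "G1S")
  expect_equal(c3$survival_remaining, 299.5) # persists, no refill
  # with the reset option the survival duration refills on escape
  kpr <- killing_params(survival_h = 5, pd = 0, survival_reset = TRUE)
  c4 <- update_target(c2, NULL, kpr, 0.5)$cell
  expect_equal(c4$survival_remaining, 300)
})

test_that("a target with no active attackers never loses survival", {
  kp <- killing_params(survival_h = 5, pd = 0)
  cell <- target_cells(1L, 0, 0, phase_remaining = 1e5, g1s_dur = 1e5,
                       g2m_dur = 40, survival_remaining = 300)
  searchers <- ctl_cells(2L, 0, 0, mode = "SEARCH") # contact but not ATTACK
  for (i in 1:50) cell <- update_target(cell, searchers, kp, 0.5)$cell
  expect_equal(cell$survival_remaining, 300)
})

test_that("CTL state machine: bonding, disabling, absorbing state", {
  kp <- killing_params(survival_h = 5, pd = 0.05, pd_ref_dt_min = 0.5)
  ctl <- ctl_cells(1L, 0, 0)
  tg <- target_cells(2L, 10, 0)
  # SEARCH + contact -> ATTACK with a bond
  up <- update_ctl(ctl, tg, 0, kp, 0.5)
  expect_equal(up$ctl$mode, "ATTACK")
  expect_equal(up$ctl$bonded_target, 2L)
  # no contact, no defense: stays SEARCH
  up2 <- update_ctl(ctl, NULL, 0, kp, 0.5)
  expect_equal(up2$ctl$mode, "SEARCH")
  # P_d = 0: never disabled
  kp0 <- killing_params(survival_h = 5, pd = 0)
  set.seed(3)
  out <- replicate(500, update_ctl(ctl, NULL, 3, kp0, 0.5)$ctl$mode)
  expect_true(all(out == "SEARCH"))
  # DISABLED is absorbing
  dis <- ctl_cells(1L, 0, 0, mode = "DISABLED")
  expect_equal(update_ctl(dis, tg, 5, kp, 0.5)$ctl$mode, "DISABLED")
})

test_that("steps to disabling follow the geometric law 1/P_d", {
  kp <- killing_params(survival_h = 5, pd = 0.05, pd_ref_dt_min = 0.5)
  ctl <- ctl_cells(1L, 0, 0)
  set.seed(4)
  trials <- 2000
  steps <- vapply(seq_len(trials), function(i) {
    s <- 0
    c2 <- ctl
    repeat {
      s <- s + 1
      c2 <- update_ctl(c2, NULL, 1, kp, 0.5)$ctl
      if (c2$mode == "DISABLED") return(s)
    }
  }, numeric(1))
  expect_equal(mean(steps), 1 / 0.05, tolerance = 0.05)
  # per-target mode: hazard compounds over m defending targets in radius
  set.seed(5)
  hit <- mean(replicate(4000, update_ctl(ctl, NULL, 3, kp, 0.5)$ctl$mode ==
                          "DISABLED"))
  expect_equal(hit, 1 - (1 - 0.05)^3, tolerance = 0.15)
})

test_that("division bookkeeping and daughter placement", {
  cyc <- cycle_phase_params(10, 0, 4, 0)
  kp <- killing_params(survival_h = 5)
  mother <- target_cells(1L, 5, -3, phase = "G2M", phase_remaining = 0,
                         g1s_dur = 600, g2m_dur = 240, mass = 2, line = 2L)
  set.seed(6)
  out <- divide_target(mother, cyc, kp, daughter_id = 99L)
  expect_equal(out$mother$mass, 1)
  expect_equal(out$mother$phase, "G1S")
  expect_equal(out$daughter$id, 99L)
  expect_equal(out$daughter$radius, mother$radius)
  expect_equal(out$daughter$line, mother$line)
  d <- sqrt((out$daughter$x - 5)^2 + (out$daughter$y + 3)^2)
  expect_equal(d, 2 * mother$radius)
  # division plane angles are uniform (chi-squared goodness of fit)
  angs <- replicate(4000, {
    o <- divide_target(mother, cyc, kp, 99L)
    atan2(o$daughter$y + 3, o$daughter$x - 5)
  })
  cnt <- table(cut(angs, breaks = seq(-pi, pi, length.out = 9)))
  expect_gt(stats::chisq.test(cnt)$p.value, 0.001)
  # calling off-schedule is a state error
  expect_error(divide_target(target_cells(1L, 0, 0), cyc, kp, 2L), "G2/M")
})
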