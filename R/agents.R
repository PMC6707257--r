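#' Draw cell-cycle phase durations
#'
#' Samples G1/S and G2/M durations from the line's normal distributions,
#' truncated at zero by resampling (at most 100 attempts, then clamped to 1%
#' of the mean). With `sd = 0` the draw is degenerate at the mean.
#'
#' @param cycle a [cycle_phase_params()] object.
#' @param n number of cells to draw for.
#' @return Data frame with columns `g1s_h`, `g2m_h` (hours), all `> 0`.
#' @export
draw_phase_durations <- function(cycle, n = 1) {
  stopifnot(inherits(cycle, "cycle_phase_params"))
  draw1 <- function(mean, sdv) {
    if (sdv <= 0) return(rep(mean, n))
    vapply(seq_len(n), function(i) {
      for (k in 1:100) {
        v <- rnorm(1, mean, sdv)
        if (v > 0) return(v)
      }
      0.01 * mean
    }, numeric(1))
  }
  data.frame(g1s_h = draw1(cycle$g1s_mean_h, cycle$g1s_sd_h),
             g2m_h = draw1(cycle$g2m_mean_h, cycle$g2m_sd_h))
}

.event <- function(type, time_min, id1 = NA_integer_, id2 = NA_integer_) {
  list(type = type, time_min = time_min, id1 = id1, id2 = id2)
}

#' Update one target cell by one time step
#'
#' Reference implementation of the target-cell state machine for a single
#' cell (the run loop applies the same rules to all agents at once).
#' With at least one active attacker the cell is in DEFENSE: its cycle timer
#' freezes and its survival duration drops by `k * dt` (k active attackers).
#' Hitting zero kills the cell (DEATH event; attacker crediting happens at the
#' engine level). With no active attackers a defending cell resumes its stored
#' cycle phase with the depleted survival duration retained (unless
#' `killing$survival_reset`); a cycling cell advances its timer, transits
#' G1S -> G2M, doubles mass across G2M, and emits DIVISION at G2M expiry.
#'
#' @param cell one-row data frame from [target_cells()].
#' @param contacting_ctl data frame of CTL in contact ([ctl_cells()] rows);
#'   only rows with `mode == "ATTACK"` count as active attackers.
#' @param killing a [killing_params()] object.
#' @param dt_min step length, minutes.
#' @return `list(cell = updated one-row data frame, events = list)`. A dead
#'   cell is returned with `phase_remaining` untouched and an added
#'   `dead = TRUE` column.
#' @export
update_target <- function(cell, contacting_ctl, killing, dt_min) {
  if (dt_min <= 0) stop("update_target: 'dt_min' must be > 0")
  stopifnot(nrow(cell) == 1, inherits(killing, "killing_params"))
  events <- list()
  k <- if (is.null(contacting_ctl) || nrow(contacting_ctl) == 0) 0L
       else sum(contacting_ctl$mode == "ATTACK")
  cell$dead <- FALSE
  if (k > 0) {
    if (cell$phase != "DEFENSE") {
      cell$stored_phase <- cell$phase
      cell$phase <- "DEFENSE"
    }
    cell$survival_remaining <- cell$survival_remaining - k * dt_min
    if (cell$survival_remaining <= 1e-9) {
      cell$survival_remaining <- 0
      cell$dead <- TRUE
      events <- c(events, list(.event("DEATH", NA_real_, cell$id, k)))
    }
  } else {
    if (cell$phase == "DEFENSE") {
      cell$phase <- cell$stored_phase
      if (killing$survival_reset) cell$survival_remaining <- killing$survival_h * 60
    }
    cell$phase_remaining <- cell$phase_remaining - dt_min
    if (cell$phase == "G1S" && cell$phase_remaining <= 0) {
      cell$phase <- "G2M"
      cell$phase_remaining <- cell$phase_remaining + cell$g2m_dur
    }
    if (cell$phase == "G2M") {
      prog <- (cell$g2m_dur - max(cell$phase_remaining, 0)) / cell$g2m_dur
      cell$mass <- min(2, 1 + prog)
      if (cell$phase_remaining <= 0)
        events <- c(events, list(.event("DIVISION", NA_real_, cell$id)))
    }
  }
  list(cell = cell, events = events)
}

#' Update one CTL by one time step
#'
#' Reference implementation of the CTL state machine for a single cell.
#' A SEARCH CTL contacting a live target adheres to the nearest one and
#' switches to ATTACK. An ATTACK CTL whose target died releases its bond and
#' resumes SEARCH. Any non-disabled CTL within the disabling radius of at
#' least one defending target is permanently DISABLED with the per-step
#' probability implied by `killing` (see [killing_params()]); DISABLED is
#' absorbing and drops any bond.
#'
#' @param ctl one-row data frame from [ctl_cells()].
#' @param contacting_targets data frame of live targets in contact (may be
#'   `NULL`); columns `id`, `x`, `y` used.
#' @param n_defending_in_radius number of DEFENSE-state targets within the
#'   disabling radius of this CTL.
#' @param killing a [killing_params()] object.
#' @param dt_min step length, minutes.
#' @param bonded_target_dead set `TRUE` when the attacked target died this
#'   step; the bond is then released (the kill is credited by the engine).
#' @return `list(ctl = updated one-row data frame, events = list)`.
#' @export
update_ctl <- function(ctl, contacting_targets, n_defending_in_radius,
                       killing, dt_min, bonded_target_dead = FALSE) {
  stopifnot(nrow(ctl) == 1, inherits(killing, "killing_params"))
  events <- list()
  if (ctl$mode == "DISABLED") return(list(ctl = ctl, events = events))
  if (ctl$mode == "ATTACK" && isTRUE(bonded_target_dead)) {
    ctl$bonded_target <- 0L
    ctl$mode <- "SEARCH"
  }
  if (ctl$mode == "SEARCH" && !is.null(contacting_targets) &&
      nrow(contacting_targets) > 0) {
    d <- sqrt((contacting_targets$x - ctl$x)^2 + (contacting_targets$y - ctl$y)^2)
    j <- order(d, contacting_targets$id)[1]
    ctl$bonded_target <- as.integer(contacting_targets$id[j])
    ctl$mode <- "ATTACK"
    events <- c(events, list(.event("BOND", NA_real_, ctl$id, ctl$bonded_target)))
  }
  if (n_defending_in_radius >= 1) {
    p1 <- .pd_step(killing, dt_min)
    p <- if (identical(killing$disable_mode, "per_target"))
      1 - (1 - p1)^n_defending_in_radius else p1
    if (runif(1) < p) {
      if (ctl$bonded_target != 0)
        events <- c(events, list(.event("UNBOND", NA_real_, ctl$id, ctl$bonded_target)))
      ctl$bonded_target <- 0L
      ctl$mode <- "DISABLED"
      events <- c(events, list(.event("DISABLE", NA_real_, ctl$id)))
    }
  }
  list(ctl = ctl, events = events)
}

#' Divide a target cell at mitosis
#'
#' Resets the mother's cycle (fresh phase durations, mass back to 1x, G1S) and
#' creates a daughter adjacent to her along a uniformly random direction at a
#' center distance of two radii. Both cells end in G1S with their own fresh
#' durations; the daughter inherits line and radius.
#'
#' @param mother one-row data frame from [target_cells()], at G2M expiry
#'   (`phase == "G2M"` and `phase_remaining <= 0`).
#' @param cycle a [cycle_phase_params()] object for the fresh draws.
#' @param killing a [killing_params()] object (daughter's survival duration).
#' @param daughter_id id for the daughter cell.
#' @return `list(mother = ..., daughter = ...)`, each a one-row data frame.
#' @export
divide_target <- function(mother, cycle, killing, daughter_id) {
  stopifnot(nrow(mother) == 1)
  if (mother$phase != "G2M" || mother$phase_remaining > 0)
    stop("divide_target: cell is not at the end of G2/M")
  dm <- draw_phase_durations(cycle, 1)
  mother$g1s_dur <- dm$g1s_h * 60
  mother$g2m_dur <- dm$g2m_h * 60
  mother$phase <- "G1S"
  mother$stored_phase <- "G1S"
  mother$phase_remaining <- mother$g1s_dur
  mother$mass <- 1
  dd <- draw_phase_durations(cycle, 1)
  ang <- runif(1, 0, 2 * pi)
  daughter <- target_cells(id = daughter_id,
                           x = mother$x + 2 * mother$radius * cos(ang),
                           y = mother$y + 2 * mother$radius * sin(ang),
                           radius = mother$radius,
                           phase = "G1S",
                           phase_remaining = dd$g1s_h * 60,
                           g1s_dur = dd$g1s_h * 60, g2m_dur = dd$g2m_h * 60,
                           survival_remaining = killing$survival_h * 60,
                           mass = 1, stored_phase = "G1S", line = mother$line)
  if ("dead" %in% names(mother)) daughter$dead <- FALSE
  list(mother = mother, daughter = daughter)
}
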