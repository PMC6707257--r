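#' Initialize a virtual culture well
#'
#' Places `initial_targets` target cells and `initial_ctl` CTL uniformly at
#' random inside a central disc just large enough to pack them (area = 1.3 x
#' total cell cross-section), mimicking the centrifugation step of the
#' experimental protocol, then relaxes overlaps by repeated force-only
#' mechanics steps until the maximum pairwise overlap is below the contact
#' tolerance. Target cells are seeded asynchronously: each starts at a
#' uniformly random elapsed position within its first cycle, emulating seeding
#' from an exponentially growing culture.
#'
#' @param params a [simulation_params()] object.
#' @param seed optional seed applied before placement (the run loop seeds
#'   itself from `params$seed`; pass a seed here only for standalone use).
#' @param max_relax_iter iteration cap for the overlap relaxation.
#' @return A `ctl_well` with clock 0.
#' @export
initialize_well <- function(params, seed = NULL, max_relax_iter = 2000) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(seed)) set.seed(seed)
  m <- params$mechanics
  nt <- params$initial_targets
  nc <- params$initial_ctl
  radii <- c(rep(m$target_radius_um, nt), rep(m$ctl_radius_um, nc))
  n <- nt + nc
  disc <- if (n > 0) sqrt(1.3 * sum(radii^2)) else 0
  if (disc + max(radii, 0) > m$well_radius_um)
    stop("initialize_well: cells cannot fit in the well (packing disc radius ",
         round(disc), " um exceeds the well)")
  u <- runif(n); ang <- runif(n, 0, 2 * pi)
  px <- disc * sqrt(u) * cos(ang)
  py <- disc * sqrt(u) * sin(ang)

  kp <- params$killing
  s_total <- kp$survival_h * 60
  line_code <- match(params$line, .lines)
  if (nt > 0) {
    dur <- draw_phase_durations(params$cycle, nt)
    g1s <- dur$g1s_h * 60
    g2m <- dur$g2m_h * 60
    elapsed <- runif(nt, 0, g1s + g2m)
    in_g1s <- elapsed < g1s
    phase <- ifelse(in_g1s, "G1S", "G2M")
    rem <- ifelse(in_g1s, g1s - elapsed, g1s + g2m - elapsed)
    mass <- ifelse(in_g1s, 1, pmin(2, 1 + (g2m - (g1s + g2m - elapsed)) / g2m))
    targets <- target_cells(id = seq_len(nt), x = px[seq_len(nt)],
                            y = py[seq_len(nt)], radius = m$target_radius_um,
                            phase = phase, phase_remaining = rem,
                            g1s_dur = g1s, g2m_dur = g2m,
                            survival_remaining = s_total, mass = mass,
                            stored_phase = phase, line = line_code)
  } else {
    targets <- target_cells(integer(0), numeric(0), numeric(0))
  }
  ctls <- if (nc > 0)
    ctl_cells(id = nt + seq_len(nc), x = px[nt + seq_len(nc)],
              y = py[nt + seq_len(nc)], radius = m$ctl_radius_um)
  else ctl_cells(integer(0), numeric(0), numeric(0))

  well <- make_well(targets, ctls)
  if (n > 1) {
    rx <- cpp_relax(.well_to_cpp(well), .cpp_cfg(params), m$contact_tol,
                    as.integer(max_relax_iter))
    well <- .well_from_cpp(rx$world)
    well$clock_min <- 0
  }
  well
}

#' Add a fresh cohort of CTL to a running well
#'
#' New CTL are seeded in SEARCH mode by the same centrifugation rule as the
#' initial population (central disc, overlap relaxation). Existing agents are
#' untouched except for the mechanical relaxation.
#'
#' @param well a `ctl_well`.
#' @param n number of CTL to add, `> 0`.
#' @param params a [simulation_params()] object.
#' @param max_relax_iter iteration cap for the overlap relaxation.
#' @return The updated `ctl_well`.
#' @export
add_ctl_cohort <- function(well, n, params, max_relax_iter = 500) {
  stopifnot(inherits(well, "ctl_well"), inherits(params, "simulation_params"))
  if (!is.numeric(n) || n <= 0) stop("add_ctl_cohort: 'n' must be > 0")
  n <- as.integer(n)
  m <- params$mechanics
  area_new <- n * m$ctl_radius_um^2
  area_old <- sum(well$targets$radius^2) + sum(well$ctls$radius^2)
  if (1.3 * (area_new + area_old) > 0.9 * m$well_radius_um^2)
    stop("add_ctl_cohort: well capacity exceeded")
  disc <- m$ctl_radius_um * sqrt(1.3 * n)
  u <- runif(n); ang <- runif(n, 0, 2 * pi)
  id0 <- .next_id(well)
  fresh <- ctl_cells(id = id0 + seq_len(n) - 1L,
                     x = disc * sqrt(u) * cos(ang),
                     y = disc * sqrt(u) * sin(ang),
                     radius = m$ctl_radius_um)
  well$ctls <- rbind(well$ctls, fresh)
  rx <- cpp_relax(.well_to_cpp(well), .cpp_cfg(params), m$contact_tol,
                  as.integer(max_relax_iter))
  out <- .well_from_cpp(rx$world)
  out$clock_min <- well$clock_min
  out
}

.event_names <- c("DEATH", "DIVISION", "DISABLE", "BOND", "UNBOND")

#' Run a full co-culture simulation
#'
#' Advances the well step by step: (1) contact detection and adhesion-bond
#' formation, (2) synchronous target updates against a frozen snapshot of
#' attackers, (3) CTL updates including disabling draws, (4) scheduled cohort
#' additions, (5) mechanics, (6) recording. Fully reproducible from
#' `params$seed`.
#'
#' @param params a [simulation_params()] object.
#' @param world optional starting `ctl_well`; by default the well is built by
#'   [initialize_well()] from `params`.
#' @param record_events keep the full event log (DEATH, DIVISION, DISABLE,
#'   BOND, UNBOND) in the result.
#' @return An object of class `"ctl_run"`: list with `series` (population
#'   time series, one row per recording time), `ledger` (per-CTL kill counts,
#'   fractional and integer credit), `events`, `final` (final well), `escaped`,
#'   `seed`, `digest`, `params`.
#' @export
run_simulation <- function(params, world = NULL, record_events = TRUE) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  if (is.null(world)) world <- initialize_well(params)
  dt <- params$mechanics$dt_min
  n_steps <- as.integer(round(params$duration_h * 60 / dt))
  rec_every <- max(1L, as.integer(round(params$record_every_min / dt)))

  # cohort additions land at the first step whose start clock >= scheduled time
  sched <- params$cohort_schedule
  cohort_steps <- integer(0); cohort_counts <- integer(0)
  if (!is.null(sched) && nrow(sched) > 0) {
    cohort_steps <- pmin(as.integer(ceiling(sched$time_h * 60 / dt)), n_steps)
    cohort_counts <- as.integer(sched$n)
  }

  initial_targets <- nrow(world$targets)
  n0 <- function(w) c(sum(w$ctls$mode == "SEARCH"), sum(w$ctls$mode == "ATTACK"),
                      sum(w$ctls$mode == "DISABLED"))
  s0 <- n0(world)
  series <- data.frame(time_min = world$clock_min, live_targets = initial_targets,
                       cum_deaths = 0, cum_divisions = 0,
                       n_search = s0[1], n_attack = s0[2], n_disabled = s0[3])
  ev_list <- list()
  cum <- c(deaths = 0, divs = 0, disabled = 0)
  next_tid <- .next_id(world)
  escaped <- FALSE
  cfg <- .cpp_cfg(params)

  bounds <- sort(unique(c(0L, cohort_steps, n_steps)))
  step_at <- 0L
  for (bi in seq_len(length(bounds))) {
    b <- bounds[bi]
    if (b > step_at) {
      out <- cpp_run(.well_to_cpp(world), cfg, b - step_at, rec_every,
                     FALSE, record_events, step_at,
                     cum["deaths"], cum["divs"], cum["disabled"], next_tid)
      world <- .well_from_cpp(out$world)
      cum <- c(deaths = out$cum_deaths, divs = out$cum_divisions,
               disabled = out$cum_disabled)
      next_tid <- out$next_target_id
      seg <- as.data.frame(out$series)
      if (nrow(seg)) {
        # keep rows on the recording grid plus the very last state
        gstep <- as.integer(round(seg$time_min / dt))
        keep <- gstep %% rec_every == 0 | gstep == n_steps | out$escaped
        series <- rbind(series, seg[keep, , drop = FALSE])
      }
      if (record_events && length(out$events$time_min))
        ev_list[[length(ev_list) + 1L]] <- as.data.frame(out$events)
      step_at <- b
      if (out$escaped) { escaped <- TRUE; break }
    }
    if (!escaped && length(cohort_steps)) {
      due <- which(cohort_steps == b)
      for (j in due) world <- add_ctl_cohort(world, cohort_counts[j], params)
    }
  }

  series <- series[!duplicated(series$time_min), , drop = FALSE]
  series$n_ctl <- series$n_search + series$n_attack + series$n_disabled
  series$per_capita <- ifelse(series$n_ctl > 0,
                              series$cum_deaths / series$n_ctl, NA_real_)
  series$time_h <- series$time_min / 60
  rownames(series) <- NULL

  # conservation must hold at every recorded step
  ok <- series$live_targets == initial_targets + series$cum_divisions - series$cum_deaths
  if (!all(ok))
    stop("run_simulation: conservation violated at t = ",
         series$time_min[which(!ok)[1]], " min")

  events <- if (length(ev_list)) {
    ev <- do.call(rbind, ev_list)
    data.frame(time_h = ev$time_min / 60,
               type = .event_names[ev$type], id1 = ev$id1, id2 = ev$id2,
               stringsAsFactors = FALSE)
  } else {
    data.frame(time_h = numeric(0), type = character(0),
               id1 = integer(0), id2 = integer(0), stringsAsFactors = FALSE)
  }

  ledger <- data.frame(ctl_id = world$ctls$id,
                       kills_frac = world$ctls$kill_frac,
                       kills_int = world$ctls$kill_int,
                       mode = world$ctls$mode, stringsAsFactors = FALSE)

  structure(list(series = series, ledger = ledger, events = events,
                 final = world, escaped = escaped,
                 initial_targets = initial_targets,
                 cum_deaths = unname(cum["deaths"]),
                 cum_divisions = unname(cum["divs"]),
                 seed = params$seed, digest = param_digest(params),
                 params = params),
            class = "ctl_run")
}

#' @export
print.ctl_run <- function(x, ...) {
  fin <- x$series[nrow(x$series), ]
  cat("<ctl_run> seed", x$seed, "digest", x$digest,
      if (x$escaped) "[ESCAPED]" else "", "\n")
  cat("  t =", round(fin$time_h, 2), "h:", fin$live_targets, "live targets (",
      x$initial_targets, "initial, +", fin$cum_divisions, "divisions, -",
      fin$cum_deaths, "deaths )\n")
  cat("  CTL:", fin$n_search, "search /", fin$n_attack, "attack /",
      fin$n_disabled, "disabled; per-capita kills",
      round(fin$per_capita, 3), "\n")
  invisible(x)
}
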