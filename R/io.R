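.config_known_keys <- list(
  top = c("simulation", "scenario", "out_dir", "seed", "log_level"),
  simulation = c("line", "duration_h", "initial_targets", "initial_ctl",
                 "et_ratio", "record_every_min", "max_pop", "seed",
                 "mechanics", "cycle", "killing", "cohort_schedule"),
  mechanics = c("spring_stiffness", "damping_coefficient",
                "repulsion_stiffness", "diffusion_coefficient", "dt_min",
                "well_radius_um", "target_radius_um", "ctl_radius_um",
                "contact_tol", "break_factor"),
  cycle = c("g1s_mean_h", "g1s_sd_h", "g2m_mean_h", "g2m_sd_h"),
  killing = c("survival_h", "rd_um", "pd", "pd_ref_dt_min", "disable_mode",
              "survival_reset"))

.check_keys <- function(x, where) {
  known <- .config_known_keys[[where]]
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("parse_config: unknown key '", bad[1], "' under '", where, "'")
  invisible(TRUE)
}

#' Parse a run configuration file
#'
#' Reads a JSON configuration mirroring [simulation_params()] (times in hours
#' at the interface). Unknown keys are rejected with the offending key named;
#' absent optional keys take package defaults, each logged unless `quiet`.
#'
#' @param path path to a JSON configuration file.
#' @param quiet suppress the applied-default log messages.
#' @return An object of class `"run_config"`: list with `params`
#'   (a `simulation_params`), `scenario` (list or `NULL`), `out_dir`,
#'   `log_level`.
#' @export
parse_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("parse_config: no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  .check_keys(cfg, "top")
  sim <- if (is.null(cfg$simulation)) list() else cfg$simulation
  .check_keys(sim, "simulation")
  note <- function(key) if (!quiet) message("parse_config: '", key,
                                            "' absent; default applied")
  sub <- function(block, name, ctor) {
    x <- sim[[name]]
    if (is.null(x)) { note(name); return(ctor()) }
    .check_keys(x, name)
    do.call(ctor, x)
  }
  mech <- sub(sim, "mechanics", mechanics_params)
  line <- if (is.null(sim$line)) { note("line"); "melanoma" } else sim$line
  cyc <- if (is.null(sim$cycle)) { note("cycle"); default_cycle_params(line) }
         else { .check_keys(sim$cycle, "cycle"); do.call(cycle_phase_params, sim$cycle) }
  kil <- if (is.null(sim$killing)) { note("killing"); default_killing_params(line) }
         else { .check_keys(sim$killing, "killing"); do.call(killing_params, sim$killing) }
  sched <- sim$cohort_schedule
  if (!is.null(sched)) sched <- as.data.frame(sched)
  getd <- function(key, default) {
    if (is.null(sim[[key]])) { note(key); default } else sim[[key]]
  }
  seed <- if (!is.null(cfg$seed)) cfg$seed else getd("seed", 1L)
  params <- simulation_params(
    line = line,
    duration_h = getd("duration_h", 18),
    initial_targets = getd("initial_targets", 1000),
    initial_ctl = sim$initial_ctl,
    et_ratio = sim$et_ratio,
    mechanics = mech, cycle = cyc, killing = kil,
    cohort_schedule = sched,
    record_every_min = getd("record_every_min", 15),
    max_pop = getd("max_pop", 1e5),
    seed = seed)
  structure(list(params = params, scenario = cfg$scenario,
                 out_dir = if (is.null(cfg$out_dir)) "." else cfg$out_dir,
                 log_level = if (is.null(cfg$log_level)) "info" else cfg$log_level),
            class = "run_config")
}

#' Write a run configuration file
#'
#' Inverse of [parse_config()]: the written file parses back to an equal
#' configuration.
#'
#' @param config a `"run_config"` object (or bare `simulation_params`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (inherits(config, "simulation_params"))
    config <- structure(list(params = config, scenario = NULL,
                             out_dir = ".", log_level = "info"),
                        class = "run_config")
  p <- config$params
  sim <- list(line = p$line, duration_h = p$duration_h,
              initial_targets = p$initial_targets,
              initial_ctl = p$initial_ctl,
              record_every_min = p$record_every_min, max_pop = p$max_pop,
              seed = p$seed,
              mechanics = unclass(p$mechanics),
              cycle = unclass(p$cycle),
              killing = unclass(p$killing))
  if (!is.null(p$cohort_schedule)) sim$cohort_schedule <- p$cohort_schedule
  out <- list(simulation = sim, out_dir = config$out_dir,
              log_level = config$log_level)
  if (!is.null(config$scenario)) out$scenario <- config$scenario
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run result to disk
#'
#' Writes the population series and per-CTL kill ledger as CSV (with a
#' commented provenance header: parameter digest, seed, package version), the
#' event log as JSON-lines, and a final-world snapshot as CSV of
#' `(id, type, x_um, y_um, state, t_h)`.
#'
#' @param result a `ctl_run`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_run_result <- function(result, dir, prefix = "run") {
  stopifnot(inherits(result, "ctl_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste0("# ctlsim ", as.character(utils::packageVersion("ctlsim"))),
           paste0("# seed ", result$seed),
           paste0("# digest ", result$digest))
  wcsv <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  paths <- c(
    wcsv(result$series, file.path(dir, paste0(prefix, "_series.csv"))),
    wcsv(result$ledger, file.path(dir, paste0(prefix, "_ledger.csv"))))
  evp <- file.path(dir, paste0(prefix, "_events.jsonl"))
  con <- file(evp, "w")
  if (nrow(result$events))
    for (i in seq_len(nrow(result$events)))
      writeLines(jsonlite::toJSON(as.list(result$events[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
  close(con)
  snap <- rbind(
    data.frame(id = result$final$targets$id, type = "target",
               x_um = result$final$targets$x, y_um = result$final$targets$y,
               state = result$final$targets$phase,
               t_h = result$final$clock_min / 60),
    data.frame(id = result$final$ctls$id, type = "ctl",
               x_um = result$final$ctls$x, y_um = result$final$ctls$y,
               state = result$final$ctls$mode,
               t_h = result$final$clock_min / 60))
  paths <- c(paths, evp,
             wcsv(snap, file.path(dir, paste0(prefix, "_snapshot.csv"))))
  invisible(paths)
}

#' Generate a synthetic reference fixture
#'
#' Stands in for experimental reference data: simulates killing curves at a
#' known "true" (R_d, P_d) over a ratio grid, adds independent Gaussian noise
#' to the percent-killed values, and simulates a 0-CTL growth-count series.
#' The truth is recorded alongside so calibration recovery can be verified.
#'
#' @param params a [simulation_params()] template (well size, mechanics).
#' @param true_rd,true_pd the generating inactivation parameters.
#' @param et_ratios ratio grid of the curves.
#' @param lines cell lines to generate.
#' @param duration_h assay duration, hours.
#' @param n_runs runs per (line, ratio).
#' @param noise_sd sd of the added noise, percentage points, `>= 0`.
#' @param growth_hours observation times of the growth series.
#' @param seed RNG seed; fixtures are reproducible from (truth, seed).
#' @param dir optional directory; when given, `curves.csv` and `growth.csv`
#'   are written in the calibration input dialect.
#' @return List with `curves` (a `killing_reference`), `growth`
#'   (per line [growth_series()] list), `truth` (list of generating values).
#' @export
generate_reference_fixture <- function(params, true_rd = 100, true_pd = 0.001,
                                       et_ratios = c(0.1, 0.5, 1.0),
                                       lines = "melanoma",
                                       duration_h = 12, n_runs = 3,
                                       noise_sd = 2, growth_hours = seq(0, 72, 24),
                                       seed = 1, dir = NULL) {
  if (noise_sd < 0) stop("generate_reference_fixture: 'noise_sd' must be >= 0")
  set.seed(seed)
  curves <- list()
  for (li in seq_along(lines)) {
    p <- params
    p$line <- lines[li]
    p$cycle <- default_cycle_params(lines[li])
    p$killing <- default_killing_params(lines[li])
    p$killing$rd_um <- true_rd
    p$killing$pd <- true_pd
    des <- assay_design(et_ratios = et_ratios, duration_h = duration_h,
                        n_runs = n_runs, line = lines[li])
    cv <- killing_assay(des, p, master_seed = derive_seed(seed, 7000 + li))
    curves[[li]] <- data.frame(line = lines[li], et_ratio = cv$et_ratio,
                               cytotoxicity = cv$pct_killed_mean +
                                 if (noise_sd > 0) rnorm(nrow(cv), 0, noise_sd)
                                 else 0,
                               measure_kind = "percent_killed",
                               stringsAsFactors = FALSE)
  }
  curves <- as_killing_reference(do.call(rbind, curves))
  growth <- lapply(seq_along(lines), function(li) {
    p <- params
    p$line <- lines[li]
    p$cycle <- default_cycle_params(lines[li])
    p$killing <- default_killing_params(lines[li])
    p$initial_ctl <- 0L
    p$duration_h <- max(growth_hours)
    p$record_every_min <- 60
    p$seed <- derive_seed(seed, 8000 + li)
    r <- run_simulation(p, record_events = FALSE)
    idx <- vapply(growth_hours, function(h) which.min(abs(r$series$time_h - h)),
                  integer(1))
    growth_series(r$series$time_h[idx], pmax(r$series$live_targets[idx], 1),
                  line = lines[li])
  })
  names(growth) <- lines
  truth <- list(rd = true_rd, pd = true_pd,
                survival_h = vapply(lines, function(l)
                  default_killing_params(l)$survival_h, numeric(1)),
                doubling_h = vapply(lines, function(l) {
                  cc <- default_cycle_params(l)
                  cc$g1s_mean_h + cc$g2m_mean_h
                }, numeric(1)),
                seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE)
    gdf <- do.call(rbind, lapply(names(growth), function(l)
      data.frame(line = l, time_h = growth[[l]]$time_h,
                 count = growth[[l]]$count)))
    write.csv(gdf, file.path(dir, "growth.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(curves = curves, growth = growth, truth = truth)
}
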