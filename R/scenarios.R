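#' Killing-assay design
#'
#' @param et_ratios effector-to-target ratios to assay, all `> 0` (0 allowed
#'   for control wells).
#' @param duration_h assay duration, hours.
#' @param n_runs independent runs per ratio.
#' @param line target cell line.
#' @return An object of class `"assay_design"`.
#' @export
assay_design <- function(et_ratios = c(0.01, 0.05, 0.1, 0.5, 1.0),
                         duration_h = 18, n_runs = 20,
                         line = c("melanoma", "conventional")) {
  line <- match.arg(line)
  if (any(et_ratios < 0)) stop("assay_design: ratios must be >= 0")
  if (n_runs < 1) stop("assay_design: 'n_runs' must be >= 1")
  structure(list(et_ratios = sort(et_ratios), duration_h = duration_h,
                 n_runs = as.integer(n_runs), line = line),
            class = "assay_design")
}

.run_for_ratio <- function(params, design, ratio, run_seed) {
  p <- params
  p$line <- design$line
  p$duration_h <- design$duration_h
  p$initial_ctl <- as.integer(round(ratio * params$initial_targets))
  p$seed <- run_seed
  run_simulation(p, record_events = FALSE)
}

#' In-silico killing assay across E/T ratios
#'
#' For each ratio, runs `design$n_runs` independent simulations and reports
#' mean and sd of the percent of initial targets killed and of the per-capita
#' kill count over the assay window.
#'
#' @param design an [assay_design()].
#' @param params a [simulation_params()] giving well size and calibrated
#'   constants; its line/duration/CTL count are overridden per the design.
#' @param master_seed seed from which each run's seed is derived.
#' @param keep_runs keep the individual `ctl_run` objects in the result.
#' @return An object of class `"killing_curve"`: data frame with one row per
#'   ratio and columns `line`, `et_ratio`, `pct_killed_mean`, `pct_killed_sd`,
#'   `per_capita_mean`, `per_capita_sd`, `n_runs`.
#' @export
killing_assay <- function(design, params, master_seed = params$seed,
                          keep_runs = FALSE) {
  stopifnot(inherits(design, "assay_design"),
            inherits(params, "simulation_params"))
  rows <- list(); runs <- list()
  for (i in seq_along(design$et_ratios)) {
    ratio <- design$et_ratios[i]
    pk <- numeric(design$n_runs); pc <- numeric(design$n_runs)
    rr <- vector("list", design$n_runs)
    for (j in seq_len(design$n_runs)) {
      r <- .run_for_ratio(params, design, ratio,
                          derive_seed(master_seed, i * 1000 + j))
      pk[j] <- 100 * r$cum_deaths / r$initial_targets
      pc[j] <- per_capita_killing(r$cum_deaths, nrow(r$final$ctls))
      if (keep_runs) rr[[j]] <- r
    }
    rows[[i]] <- data.frame(line = design$line, et_ratio = ratio,
                            pct_killed_mean = mean(pk),
                            pct_killed_sd = if (design$n_runs > 1) sd(pk) else 0,
                            per_capita_mean = if (ratio > 0) mean(pc) else NA_real_,
                            per_capita_sd = if (ratio > 0 && design$n_runs > 1)
                              sd(pc) else NA_real_,
                            n_runs = design$n_runs, stringsAsFactors = FALSE)
    if (keep_runs) runs[[i]] <- rr
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$et_ratio), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("killing_curve", "data.frame")
  if (keep_runs) attr(out, "runs") <- runs
  out
}

#' Search for the optimal E/T ratio
#'
#' Evaluates every ratio on the grid `seq(ratio_min, ratio_max, by = step)`
#' and returns the smallest ratio whose mean final live-target count over
#' `n_runs` runs does not exceed the initial count, i.e. the cheapest CTL
#' dose that nets out tumor growth over the window.
#'
#' @param params a [simulation_params()].
#' @param ratio_min,ratio_max,step the sampling grid (default 0.5 to 1.0 in
#'   steps of 0.005: 101 candidate ratios).
#' @param duration_h assay duration, hours.
#' @param n_runs runs per candidate ratio.
#' @param master_seed seed for run-seed derivation.
#' @return An object of class `"ratio_sweep"`: list with `optimal_ratio`
#'   (`NA` if no grid ratio controls growth), `mean_final_targets`,
#'   `sd_final_targets`, `controlled` flag and the full `table` of per-ratio
#'   results.
#' @export
optimal_ratio_search <- function(params, ratio_min = 0.5, ratio_max = 1.0,
                                 step = 0.005, duration_h = 18, n_runs = 20,
                                 master_seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  if (ratio_min >= ratio_max) stop("optimal_ratio_search: ratio_min < ratio_max required")
  if (step <= 0) stop("optimal_ratio_search: 'step' must be > 0")
  grid <- seq(ratio_min, ratio_max, by = step)
  des <- assay_design(et_ratios = 1, duration_h = duration_h, n_runs = 1,
                      line = params$line)
  tab <- data.frame(et_ratio = grid, mean_final = NA_real_, sd_final = NA_real_)
  for (i in seq_along(grid)) {
    fin <- numeric(n_runs)
    for (j in seq_len(n_runs)) {
      r <- .run_for_ratio(params, des, grid[i],
                          derive_seed(master_seed, i * 1000 + j))
      fin[j] <- r$series$live_targets[nrow(r$series)]
    }
    tab$mean_final[i] <- mean(fin)
    tab$sd_final[i] <- if (n_runs > 1) sd(fin) else 0
  }
  ok <- which(tab$mean_final <= params$initial_targets)
  if (length(ok) == 0) {
    res <- list(optimal_ratio = NA_real_, mean_final_targets = NA_real_,
                sd_final_targets = NA_real_, controlled = FALSE, table = tab)
  } else {
    i <- min(ok)
    res <- list(optimal_ratio = grid[i], mean_final_targets = tab$mean_final[i],
                sd_final_targets = tab$sd_final[i], controlled = TRUE, table = tab)
  }
  structure(res, class = "ratio_sweep")
}

#' @export
print.ratio_sweep <- function(x, ...) {
  if (x$controlled)
    cat("<ratio_sweep> optimal E/T ratio", x$optimal_ratio, "with",
        round(x$mean_final_targets, 2), "+/-", round(x$sd_final_targets, 2),
        "targets remaining\n")
  else cat("<ratio_sweep> growth not controlled on the sampled grid\n")
  invisible(x)
}

#' Prolonged co-culture experiment
#'
#' Mean (and sd) live-target trajectories over long horizons (default 360 h /
#' 15 days) for each E/T ratio. Runs whose target population exceeds
#' `params$max_pop` are truncated and flagged escaped, not an error.
#'
#' @param params a [simulation_params()].
#' @param et_ratios ratios to compare.
#' @param duration_h horizon, hours.
#' @param n_runs runs per ratio.
#' @param master_seed seed for run-seed derivation.
#' @return Data frame with columns `et_ratio`, `time_h`, `mean_live`,
#'   `sd_live`, `n_escaped`.
#' @export
long_term_experiment <- function(params, et_ratios, duration_h = 360,
                                 n_runs = 20, master_seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  out <- list()
  for (i in seq_along(et_ratios)) {
    des <- assay_design(et_ratios = et_ratios[i], duration_h = duration_h,
                        n_runs = 1, line = params$line)
    mats <- list(); esc <- 0L
    for (j in seq_len(n_runs)) {
      r <- .run_for_ratio(params, des, et_ratios[i],
                          derive_seed(master_seed, i * 1000 + j))
      if (r$escaped) esc <- esc + 1L
      mats[[j]] <- r$series[, c("time_h", "live_targets")]
    }
    times <- sort(unique(unlist(lapply(mats, `[[`, "time_h"))))
    live <- sapply(mats, function(m) {
      # escaped runs hold their last value (population beyond the cap)
      stats::approx(m$time_h, m$live_targets, xout = times, method = "constant",
                    rule = 2)$y
    })
    live <- matrix(live, nrow = length(times))
    out[[i]] <- data.frame(et_ratio = et_ratios[i], time_h = times,
                           mean_live = rowMeans(live),
                           sd_live = apply(live, 1, sd),
                           n_escaped = esc)
  }
  do.call(rbind, out)
}

#' Sequential CTL cohort schedule
#'
#' @param time_h addition times, hours, non-decreasing.
#' @param n cohort sizes, all `> 0`.
#' @return An object of class `"cohort_schedule"` (data frame with a
#'   `total_ctl` attribute).
#' @export
cohort_schedule <- function(time_h, n) {
  if (length(time_h) != length(n)) stop("cohort_schedule: lengths differ")
  if (is.unsorted(time_h)) stop("cohort_schedule: times must be non-decreasing")
  if (any(n <= 0)) stop("cohort_schedule: cohort sizes must be > 0")
  out <- data.frame(time_h = time_h, n = as.integer(n))
  attr(out, "total_ctl") <- sum(out$n)
  class(out) <- c("cohort_schedule", "data.frame")
  out
}

#' Sequential-addition versus single-bolus comparison
#'
#' Runs each sequential schedule and a single-bolus comparator carrying the
#' same total number of CTL, and compares final live-target counts with
#' two-sided rank-sum tests. Schedules whose totals differ from `bolus_total`
#' are a configuration error: the comparison is only meaningful at equal CTL
#' numbers.
#'
#' @param params a [simulation_params()] (its `initial_ctl` is ignored; arms
#'   define their own dosing).
#' @param schedules list of [cohort_schedule()] objects.
#' @param bolus_total CTL count of the bolus arm, all present at t = 0.
#' @param duration_h horizon of the comparison, hours.
#' @param n_runs runs per arm.
#' @param master_seed seed for run-seed derivation.
#' @return An object of class `"sequential_comparison"`: list with `arms`
#'   (per-arm summary data frame), `final_counts` (per-run outcomes by arm)
#'   and `tests` (rank-sum statistic and p-value of each schedule vs bolus).
#' @export
sequential_addition_experiment <- function(params, schedules, bolus_total,
                                           duration_h = 72, n_runs = 20,
                                           master_seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  if (inherits(schedules, "cohort_schedule")) schedules <- list(schedules)
  totals <- vapply(schedules, function(s) sum(s$n), numeric(1))
  if (any(totals != bolus_total))
    stop("sequential_addition_experiment: schedule totals (",
         paste(totals, collapse = ", "), ") must equal the bolus total (",
         bolus_total, ")")

  run_arm <- function(schedule, arm_idx) {
    vapply(seq_len(n_runs), function(j) {
      p <- params
      p$duration_h <- duration_h
      p$seed <- derive_seed(master_seed, arm_idx * 1000 + j)
      if (is.null(schedule)) { # bolus
        p$initial_ctl <- as.integer(bolus_total)
        p$cohort_schedule <- NULL
      } else {
        at0 <- schedule$time_h == 0
        p$initial_ctl <- as.integer(sum(schedule$n[at0]))
        rest <- schedule[!at0, , drop = FALSE]
        p$cohort_schedule <- if (nrow(rest)) as.data.frame(rest) else NULL
      }
      r <- run_simulation(p, record_events = FALSE)
      r$series$live_targets[nrow(r$series)]
    }, numeric(1))
  }

  bolus <- run_arm(NULL, 0)
  arms <- list(bolus = bolus)
  tests <- list()
  for (s in seq_along(schedules)) {
    nm <- paste0("schedule_", s)
    arms[[nm]] <- run_arm(schedules[[s]], s)
    ts <- rank_sum_test(arms[[nm]], bolus)
    tests[[nm]] <- data.frame(arm = nm, statistic = ts$statistic,
                              p_value = ts$p_value, method = ts$method,
                              stringsAsFactors = FALSE)
  }
  summary_df <- data.frame(arm = names(arms),
                           mean_final = vapply(arms, mean, numeric(1)),
                           sd_final = vapply(arms, sd, numeric(1)),
                           n_runs = n_runs, stringsAsFactors = FALSE)
  rownames(summary_df) <- NULL
  structure(list(arms = summary_df, final_counts = arms,
                 tests = do.call(rbind, tests)),
            class = "sequential_comparison")
}

#' @export
print.sequential_comparison <- function(x, ...) {
  cat("<sequential_comparison>\n")
  print(x$arms, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("rank-sum vs bolus:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}
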