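#' Growth-count series
#'
#' Observed live-cell counts of an unchallenged culture, used to calibrate the
#' cell-cycle duration.
#'
#' @param time_h observation times, hours, strictly increasing.
#' @param count live-cell counts, all `> 0`.
#' @param line cell line label.
#' @return An object of class `"growth_series"`.
#' @export
growth_series <- function(time_h, count, line = "melanoma") {
  if (length(time_h) != length(count)) stop("growth_series: lengths differ")
  if (is.unsorted(time_h, strictly = TRUE))
    stop("growth_series: times must be strictly increasing")
  if (any(count <= 0)) stop("growth_series: counts must be > 0")
  structure(list(time_h = time_h, count = count, line = line,
                 initial_count = count[1]), class = "growth_series")
}

#' Fit cell-cycle duration from exponential growth counts
#'
#' Log-linear regression of count on time gives the doubling time; the mean
#' total cycle duration is taken equal to it and split into G1/S and G2/M by
#' `phase_split`, with sds equal to `sd_frac` of each mean.
#'
#' @param series a [growth_series()] with at least 3 observations.
#' @param phase_split fraction of the cycle spent in G1/S.
#' @param sd_frac sd of each phase as a fraction of its mean.
#' @return List with `cycle` (a [cycle_phase_params()], or `NULL` for a flat
#'   series), `doubling_time_h` (`Inf` sentinel if the series does not grow),
#'   `r_squared`, `flat` flag.
#' @export
fit_growth <- function(series, phase_split = 0.75, sd_frac = 0.10) {
  stopifnot(inherits(series, "growth_series"))
  if (length(series$count) < 3)
    stop("fit_growth: need at least 3 observations")
  if (is.unsorted(series$count)) {
    if (any(diff(series$count) < 0))
      warning("fit_growth: decreasing counts; fitting anyway")
  }
  fit <- lm(log2(count) ~ time_h,
            data = data.frame(time_h = series$time_h, count = series$count))
  slope <- unname(coef(fit)[2])
  # summary.lm warns on an exactly exponential series; the fit is still valid
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (slope <= 1e-9) {
    warning("fit_growth: flat or declining series; doubling time = Inf")
    return(list(cycle = NULL, doubling_time_h = Inf, r_squared = r2,
                flat = TRUE))
  }
  td <- 1 / slope
  cyc <- cycle_phase_params(g1s_mean_h = phase_split * td,
                            g1s_sd_h = sd_frac * phase_split * td,
                            g2m_mean_h = (1 - phase_split) * td,
                            g2m_sd_h = sd_frac * (1 - phase_split) * td)
  list(cycle = cyc, doubling_time_h = td, r_squared = r2, flat = FALSE)
}

#' Reference killing-curve table
#'
#' Normalizes a reference cytotoxicity table to the percent-killed scale used
#' by the simulator. Rows with `measure_kind == "fold_over_basal"` are
#' converted using the per-line basal death fraction:
#' `percent = fold * basal_fraction * 100`.
#'
#' @param df data frame with columns `line`, `et_ratio`, `cytotoxicity` and
#'   optionally `measure_kind` (`"percent_killed"` default or
#'   `"fold_over_basal"`) and `basal_fraction`.
#' @param default_basal_fraction basal death fraction used (with a warning)
#'   when a fold-change row carries no `basal_fraction`.
#' @return Data frame `line`, `et_ratio`, `cytotoxicity` (percent killed),
#'   class `"killing_reference"`.
#' @export
as_killing_reference <- function(df, default_basal_fraction = 0.05) {
  df <- as.data.frame(df)
  need <- c("line", "et_ratio", "cytotoxicity")
  if (!all(need %in% names(df)))
    stop("as_killing_reference: need columns ", paste(need, collapse = ", "))
  if (!"measure_kind" %in% names(df)) df$measure_kind <- "percent_killed"
  fold <- df$measure_kind == "fold_over_basal"
  if (any(fold)) {
    if (!"basal_fraction" %in% names(df)) {
      warning("as_killing_reference: no basal_fraction column; using default ",
              default_basal_fraction)
      df$basal_fraction <- default_basal_fraction
    }
    bf <- ifelse(is.na(df$basal_fraction), default_basal_fraction,
                 df$basal_fraction)
    df$cytotoxicity[fold] <- df$cytotoxicity[fold] * bf[fold] * 100
  }
  out <- df[, need]
  out <- out[order(out$line, out$et_ratio), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("killing_reference", "data.frame")
  out
}

#' Mean-square distance between two killing curves
#'
#' Mean over all shared (line, E/T ratio) cells of the squared difference in
#' percent cytotoxicity. Symmetric; zero iff the curves agree on every cell.
#'
#' @param simulated a `killing_curve` from [killing_assay()] (or any data
#'   frame with `line`, `et_ratio` and `pct_killed_mean` or `cytotoxicity`).
#' @param reference a [as_killing_reference()] table on the same grid.
#' @return Non-negative scalar score.
#' @export
mse_distance <- function(simulated, reference) {
  getcol <- function(d) {
    if ("pct_killed_mean" %in% names(d)) d$pct_killed_mean else d$cytotoxicity
  }
  s <- data.frame(line = simulated$line, et_ratio = simulated$et_ratio,
                  v = getcol(simulated))
  r <- data.frame(line = reference$line, et_ratio = reference$et_ratio,
                  v = getcol(reference))
  m <- merge(s, r, by = c("line", "et_ratio"))
  if (nrow(m) != nrow(s) || nrow(m) != nrow(r))
    stop("mse_distance: curves are not on the same (line, et_ratio) grid")
  mean((m$v.x - m$v.y)^2)
}

#' Calibration grid for the inactivation parameters
#'
#' The sampled ranges of the disabling radius R_d and disabling probability
#' P_d. Defaults reproduce the reference sampling: R_d from 50 to 400 um in
#' steps of 12.5 (29 values) and P_d from 0.00025 to 0.01 in steps of 0.00025
#' (40 values), 1160 couples.
#'
#' @param rd_values candidate R_d values, um.
#' @param pd_values candidate P_d values.
#' @param runs_per_point simulation runs per line, ratio and grid point.
#' @return An object of class `"calibration_grid"`.
#' @export
calibration_grid <- function(rd_values = seq(50, 400, by = 12.5),
                             pd_values = seq(0.00025, 0.01, by = 0.00025),
                             runs_per_point = 10) {
  if (any(rd_values < 0) || any(pd_values < 0) || any(pd_values > 1))
    stop("calibration_grid: invalid grid values")
  structure(list(rd_values = sort(rd_values), pd_values = sort(pd_values),
                 runs_per_point = as.integer(runs_per_point),
                 scores = NULL, best = NULL),
            class = "calibration_grid")
}

#' Grid search of (R_d, P_d) against reference killing curves
#'
#' Simulates the killing assay at every (R_d, P_d) couple of the grid —
#' `runs_per_point` runs per cell line and E/T ratio — scores each couple by
#' [mse_distance()] to the reference, and selects the minimum. Ties are
#' broken toward smaller P_d, then smaller R_d.
#'
#' @param grid a [calibration_grid()].
#' @param reference a [as_killing_reference()] table covering the assayed
#'   ratios for every assayed line.
#' @param params a [simulation_params()] carrying everything but R_d / P_d.
#' @param et_ratios ratios to assay (default: the ratios in `reference`).
#' @param lines lines to assay (default: the lines in `reference`).
#' @param duration_h assay duration, hours.
#' @param master_seed seed for run-seed derivation.
#' @return The grid with `scores` (data frame `rd`, `pd`, `score`) and
#'   `best` (`list(rd, pd, score)`) filled in.
#' @export
grid_search_rd_pd <- function(grid, reference, params,
                              et_ratios = sort(unique(reference$et_ratio)),
                              lines = sort(unique(reference$line)),
                              duration_h = 18, master_seed = params$seed) {
  stopifnot(inherits(grid, "calibration_grid"),
            inherits(params, "simulation_params"))
  combos <- expand.grid(pd = grid$pd_values, rd = grid$rd_values)[, c("rd", "pd")]
  scores <- numeric(nrow(combos))
  ref <- reference[reference$line %in% lines &
                     reference$et_ratio %in% et_ratios, , drop = FALSE]
  for (i in seq_len(nrow(combos))) {
    sim <- list()
    for (li in seq_along(lines)) {
      p <- params
      p$line <- lines[li]
      p$cycle <- default_cycle_params(lines[li])
      p$killing <- default_killing_params(lines[li])
      p$killing$rd_um <- combos$rd[i]
      p$killing$pd <- combos$pd[i]
      des <- assay_design(et_ratios = et_ratios, duration_h = duration_h,
                          n_runs = grid$runs_per_point, line = lines[li])
      sim[[li]] <- killing_assay(des, p,
                                 master_seed = derive_seed(master_seed,
                                                           i * 100 + li))
    }
    sim <- do.call(rbind, sim)
    scores[i] <- mse_distance(sim, ref)
  }
  combos$score <- scores
  # argmin with ties broken toward smaller pd, then smaller rd
  ord <- order(combos$score, combos$pd, combos$rd)
  best <- combos[ord[1], ]
  grid$scores <- combos
  grid$best <- list(rd = best$rd, pd = best$pd, score = best$score)
  grid
}

#' @export
print.calibration_grid <- function(x, ...) {
  cat("<calibration_grid>", length(x$rd_values), "x", length(x$pd_values),
      "couples,", x$runs_per_point, "runs/point\n")
  if (!is.null(x$best))
    cat("  best: R_d =", x$best$rd, "um, P_d =", x$best$pd,
        " (mse", signif(x$best$score, 4), ")\n")
  invisible(x)
}
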