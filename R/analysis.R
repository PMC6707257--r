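#' Per-capita killing
#'
#' The population-level per-capita kill count `k_ctl = n_kt / n_ctl`, targets
#' killed divided by the number of CTL.
#'
#' @param n_kt number of target cells killed, `>= 0`.
#' @param n_ctl number of CTL.
#' @return The exact quotient, or `NA_real_` when `n_ctl` is 0.
#' @export
per_capita_killing <- function(n_kt, n_ctl) {
  if (any(n_kt < 0)) stop("per_capita_killing: 'n_kt' must be >= 0")
  ifelse(n_ctl > 0, n_kt / n_ctl, NA_real_)
}

#' Repartition of kill counts over the CTL population
#'
#' Pools the integer-credit kill ledger of one or more runs into a normalized
#' histogram of kills per CTL (bin width one kill), the population repartition
#' of killing efficacy.
#'
#' @param results a `ctl_run` or list of `ctl_run` objects sharing one E/T
#'   design.
#' @param use chooses the ledger; only the integer-credit ledger
#'   (`"kills_int"`) yields integer bins, passing `"kills_frac"` is an error.
#' @return An object of class `"kill_repartition"`: list with `histogram`
#'   (named fractions summing to 1), `fraction_gt5` (share of CTL with more
#'   than 5 kills), `max_kills`, `n_ctl`, `n_runs`.
#' @export
kill_repartition <- function(results, use = "kills_int") {
  if (!identical(use, "kills_int"))
    stop("kill_repartition: integer-credit ledger required (use = \"kills_int\")")
  if (inherits(results, "ctl_run")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "ctl_run")))
  kills <- unlist(lapply(results, function(r) r$ledger$kills_int))
  if (length(kills) == 0)
    return(structure(list(histogram = numeric(0), fraction_gt5 = NA_real_,
                          max_kills = NA_integer_, n_ctl = 0L,
                          n_runs = length(results)),
                     class = "kill_repartition"))
  tab <- table(factor(kills, levels = 0:max(kills)))
  hist <- as.numeric(tab) / length(kills)
  names(hist) <- names(tab)
  structure(list(histogram = hist,
                 fraction_gt5 = mean(kills > 5),
                 max_kills = max(kills),
                 n_ctl = length(kills),
                 n_runs = length(results)),
            class = "kill_repartition")
}

#' @export
print.kill_repartition <- function(x, ...) {
  cat("<kill_repartition>", x$n_ctl, "CTL pooled over", x$n_runs, "runs; ",
      "max", x$max_kills, "kills;", round(100 * x$fraction_gt5, 1),
      "% killed > 5 targets\n")
  invisible(x)
}

#' Temporal per-capita killing statistics
#'
#' Cumulative kills at each recorded time divided by the CTL present at that
#' time ("real-time" per-capita killing). The denominator steps up at cohort
#' arrivals, so the series can drop discontinuously there; it is
#' non-decreasing between additions.
#'
#' @param result a `ctl_run`.
#' @return Data frame with columns `time_h`, `n_kt`, `n_ctl`, `k_ctl`.
#' @export
temporal_per_capita <- function(result) {
  stopifnot(inherits(result, "ctl_run"))
  s <- result$series
  data.frame(time_h = s$time_h, n_kt = s$cum_deaths, n_ctl = s$n_ctl,
             k_ctl = per_capita_killing(s$cum_deaths, s$n_ctl))
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Two-sample Mann-Whitney / Wilcoxon rank-sum test. For combined sample
#' sizes up to `exact_max` (and no ties) the two-sided p-value is computed by
#' exact enumeration of all rank assignments; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param a,b numeric samples, both non-empty.
#' @param exact_max largest combined size for the exact branch.
#' @return `list(statistic = W of sample a, p_value = two-sided p,
#'   method = "exact" | "normal")`.
#' @export
rank_sum_test <- function(a, b, exact_max = 12) {
  if (length(a) == 0 || length(b) == 0)
    stop("rank_sum_test: both samples must be non-empty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # Mann-Whitney U of sample a
  ties <- any(duplicated(pooled))
  if (length(unique(pooled)) == 1) {
    warning("rank_sum_test: all values identical; p = 1")
    return(list(statistic = w, p_value = 1, method = "ties"))
  }
  if (n1 + n2 <= exact_max && !ties) {
    # enumerate every choice of n1 ranks among n1 + n2
    combs <- combn(n1 + n2, n1)
    ws <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(ws - mu) >= abs(w - mu) - 1e-12)
    return(list(statistic = w, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2) # continuity correction
  p <- min(1, 2 * pnorm(-abs(z)))
  list(statistic = w, p_value = p, method = "normal")
}
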