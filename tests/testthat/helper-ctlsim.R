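# shared fixture builders; all worlds are generated in code at test time

# small calibrated well, sized for fast tests
small_params <- function(line = "melanoma", n_targets = 60, et_ratio = 0,
                         duration_h = 2, seed = 1, ...) {
  default_params(line, initial_targets = n_targets, et_ratio = et_ratio,
                 duration_h = duration_h, record_every_min = 30,
                 seed = seed, ...)
}

# a frozen 1-target / k-CTL conjugate with motility off and no inactivation:
# the analytic death-time scenario
pinned_world <- function(k = 1, survival_min = 300) {
  tg <- target_cells(1L, 0, 0, phase_remaining = 1e6, g1s_dur = 1e6,
                     g2m_dur = 300, survival_remaining = survival_min)
  ang <- 2 * pi * seq_len(k) / k
  ct <- ctl_cells(1L + seq_len(k), 13 * cos(ang), 13 * sin(ang))
  make_well(tg, ct)
}

pinned_params <- function(survival_min = 300, duration_h = 8, pd = 0,
                          seed = 42) {
  default_params("melanoma",
                 mechanics = mechanics_params(diffusion_coefficient = 0),
                 killing = killing_params(survival_h = survival_min / 60,
                                          pd = pd),
                 duration_h = duration_h, initial_targets = 0,
                 initial_ctl = 0, seed = seed)
}

# random agent cloud for neighbor/contact oracles
random_world <- function(n_targets, n_ctl, extent = 150, seed = 1) {
  set.seed(seed)
  n <- n_targets + n_ctl
  x <- runif(n, -extent, extent)
  y <- runif(n, -extent, extent)
  tg <- target_cells(seq_len(n_targets), x[seq_len(n_targets)],
                     y[seq_len(n_targets)])
  ct <- ctl_cells(n_targets + seq_len(n_ctl), x[n_targets + seq_len(n_ctl)],
                  y[n_targets + seq_len(n_ctl)])
  make_well(tg, ct)
}

# O(n^2) oracles
brute_neighbors <- function(well, position, radius) {
  x <- c(well$targets$x, well$ctls$x)
  y <- c(well$targets$y, well$ctls$y)
  ids <- c(well$targets$id, well$ctls$id)
  d <- sqrt((x - position[1])^2 + (y - position[2])^2)
  sort(ids[d <= radius])
}

brute_contacts <- function(well, tol = 0.05) {
  x <- c(well$targets$x, well$ctls$x)
  y <- c(well$targets$y, well$ctls$y)
  r <- c(well$targets$radius, well$ctls$radius)
  ids <- c(well$targets$id, well$ctls$id)
  out <- list()
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d <= (r[i] + r[j]) * (1 + tol))
      out[[length(out) + 1]] <- c(min(ids[i], ids[j]), max(ids[i], ids[j]))
  }
  if (!length(out)) return(data.frame(a = integer(0), b = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(a = m[, 1], b = m[, 2])
  df[order(df$a, df$b), , drop = FALSE]
}

# fake minimal ctl_run for analysis-level unit tests
fake_run <- function(kills_int, series = NULL) {
  structure(list(ledger = data.frame(ctl_id = seq_along(kills_int),
                                     kills_frac = kills_int,
                                     kills_int = as.integer(kills_int),
                                     mode = "SEARCH"),
                 series = series),
            class = "ctl_run")
}
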