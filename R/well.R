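#' @useDynLib ctlsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd lm coef cor.test pnorm var
#' @importFrom utils head read.csv write.csv combn
NULL

.phase_levels <- c("G1S", "G2M", "DEFENSE")
.mode_levels <- c("SEARCH", "ATTACK", "DISABLED")

#' Construct a target-cell state table
#'
#' Helper to build the `targets` component of a well; mostly useful for tests
#' and hand-crafted scenarios. All times in minutes, positions in um.
#'
#' @param id integer ids (unique across the whole well).
#' @param x,y positions, um.
#' @param radius cell radius, um.
#' @param phase `"G1S"`, `"G2M"` or `"DEFENSE"`.
#' @param phase_remaining time left in the current cycle phase, minutes.
#' @param g1s_dur,g2m_dur this cell's drawn phase durations, minutes.
#' @param survival_remaining remaining survival duration, minutes.
#' @param mass relative mass (1 at birth, 2 at mitosis).
#' @param stored_phase cycle phase to resume after defense.
#' @param line 1 = conventional, 2 = melanoma.
#' @return A data frame with one row per target cell.
#' @export
target_cells <- function(id, x, y, radius = 8, phase = "G1S",
                         phase_remaining = 900, g1s_dur = 900, g2m_dur = 300,
                         survival_remaining = 327, mass = 1,
                         stored_phase = "G1S", line = 2L) {
  n <- length(id)
  rl <- function(v) rep_len(v, n)
  df <- data.frame(id = as.integer(id), x = rl(x), y = rl(y),
                   radius = rl(radius),
                   mass = rl(mass), phase = rl(phase),
                   stored_phase = rl(stored_phase),
                   phase_remaining = rl(phase_remaining),
                   g1s_dur = rl(g1s_dur), g2m_dur = rl(g2m_dur),
                   survival_remaining = rl(survival_remaining),
                   line = as.integer(rl(line)),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$phase %in% .phase_levels),
            all(df$stored_phase %in% .phase_levels[1:2]))
  df
}

#' Construct a CTL state table
#'
#' @param id integer ids (unique across the whole well).
#' @param x,y positions, um.
#' @param radius cell radius, um.
#' @param mode `"SEARCH"`, `"ATTACK"` or `"DISABLED"`.
#' @param bonded_target id of the attacked target (0 = none; non-zero iff
#'   `mode == "ATTACK"`).
#' @param kill_frac,kill_int fractional-credit and integer-credit kill ledgers.
#' @param bond_step step index at which the current bond formed.
#' @return A data frame with one row per CTL.
#' @export
ctl_cells <- function(id, x, y, radius = 5, mode = "SEARCH",
                      bonded_target = 0L, kill_frac = 0, kill_int = 0L,
                      bond_step = 0L) {
  n <- length(id)
  rl <- function(v) rep_len(v, n)
  df <- data.frame(id = as.integer(id), x = rl(x), y = rl(y),
                   radius = rl(radius),
                   mode = rl(mode), kill_frac = rl(kill_frac),
                   kill_int = as.integer(rl(kill_int)),
                   bonded_target = as.integer(rl(bonded_target)),
                   bond_step = as.integer(rl(bond_step)),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$mode %in% .mode_levels))
  df
}

empty_bonds <- function() {
  data.frame(a = integer(0), b = integer(0), rest_length = numeric(0))
}

#' Assemble a well state
#'
#' A `ctl_well` holds the full simulation world at one instant: the clock, all
#' target cells and CTL, and the target-target adhesion bonds (CTL-target
#' attack bonds are carried on the CTL rows as `bonded_target`).
#'
#' @param targets data frame from [target_cells()] (or zero-row equivalent).
#' @param ctls data frame from [ctl_cells()].
#' @param bonds data frame with columns `a`, `b`, `rest_length`; target ids.
#' @param clock_min current simulated time, minutes.
#' @return An object of class `"ctl_well"`.
#' @export
make_well <- function(targets = target_cells(integer(0), numeric(0), numeric(0)),
                      ctls = ctl_cells(integer(0), numeric(0), numeric(0)),
                      bonds = empty_bonds(), clock_min = 0) {
  ids <- c(targets$id, ctls$id)
  if (anyDuplicated(ids)) stop("make_well: agent ids must be unique across the well")
  if (nrow(bonds)) {
    if (any(bonds$a == bonds$b)) stop("make_well: a bond cannot link an agent to itself")
    if (!all(c(bonds$a, bonds$b) %in% targets$id))
      stop("make_well: target-target bonds must reference live target ids")
    key <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
    if (anyDuplicated(key)) stop("make_well: at most one bond per unordered pair")
  }
  bad <- ctls$bonded_target != 0 & !(ctls$bonded_target %in% targets$id)
  if (any(bad)) stop("make_well: bonded_target must reference a live target")
  if (any((ctls$bonded_target != 0) != (ctls$mode == "ATTACK")))
    stop("make_well: bonded_target must be set iff mode is ATTACK")
  structure(list(clock_min = clock_min, targets = targets, ctls = ctls,
                 bonds = bonds), class = "ctl_well")
}

# ---- R <-> C++ world encoding -------------------------------------------

.well_to_cpp <- function(well) {
  tg <- well$targets
  ct <- well$ctls
  list(clock = well$clock_min,
       targets = list(id = tg$id, x = tg$x, y = tg$y, radius = tg$radius,
                      mass = tg$mass,
                      phase = match(tg$phase, .phase_levels),
                      stored_phase = match(tg$stored_phase, .phase_levels),
                      phase_remaining = tg$phase_remaining,
                      g1s_dur = tg$g1s_dur, g2m_dur = tg$g2m_dur,
                      survival_remaining = tg$survival_remaining,
                      line = tg$line),
       ctls = list(id = ct$id, x = ct$x, y = ct$y, radius = ct$radius,
                   mode = match(ct$mode, .mode_levels),
                   kill_frac = ct$kill_frac, kill_int = ct$kill_int,
                   bonded_target = ct$bonded_target, bond_step = ct$bond_step),
       bonds = list(a = well$bonds$a, b = well$bonds$b,
                    rest_length = well$bonds$rest_length))
}

.well_from_cpp <- function(w) {
  tg <- w$targets
  ct <- w$ctls
  targets <- data.frame(id = tg$id, x = tg$x, y = tg$y, radius = tg$radius,
                        mass = tg$mass,
                        phase = .phase_levels[tg$phase],
                        stored_phase = .phase_levels[tg$stored_phase],
                        phase_remaining = tg$phase_remaining,
                        g1s_dur = tg$g1s_dur, g2m_dur = tg$g2m_dur,
                        survival_remaining = tg$survival_remaining,
                        line = tg$line, stringsAsFactors = FALSE)
  ctls <- data.frame(id = ct$id, x = ct$x, y = ct$y, radius = ct$radius,
                     mode = .mode_levels[ct$mode],
                     kill_frac = ct$kill_frac, kill_int = ct$kill_int,
                     bonded_target = ct$bonded_target, bond_step = ct$bond_step,
                     stringsAsFactors = FALSE)
  bonds <- data.frame(a = w$bonds$a, b = w$bonds$b,
                      rest_length = w$bonds$rest_length)
  structure(list(clock_min = w$clock, targets = targets, ctls = ctls,
                 bonds = bonds), class = "ctl_well")
}

#' @export
print.ctl_well <- function(x, ...) {
  cat("<ctl_well> t =", x$clock_min, "min |", nrow(x$targets), "targets,",
      nrow(x$ctls), "CTL (",
      sum(x$ctls$mode == "SEARCH"), "search /",
      sum(x$ctls$mode == "ATTACK"), "attack /",
      sum(x$ctls$mode == "DISABLED"), "disabled ),",
      nrow(x$bonds), "adhesions\n")
  invisible(x)
}
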