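#' Brownian displacement over one time step
#'
#' Draws an isotropic 2-D Brownian displacement with zero mean and per-axis
#' variance `2 * D * dt`, the motility model of searching CTL.
#'
#' @param diffusion_coefficient D, um^2/min, `>= 0`.
#' @param dt_min step length, minutes, `> 0`.
#' @param n number of displacements to draw.
#' @return An `n x 2` matrix of displacements (um).
#' @export
brownian_displacement <- function(diffusion_coefficient, dt_min, n = 1) {
  if (diffusion_coefficient < 0) stop("brownian_displacement: D must be >= 0")
  if (dt_min <= 0) stop("brownian_displacement: dt must be > 0")
  sdv <- sqrt(2 * diffusion_coefficient * dt_min)
  matrix(rnorm(2 * n, 0, sdv), ncol = 2)
}

#' Advance the mechanics by one time step
#'
#' Applies one overdamped update: spring forces along every adhesion bond
#' toward its rest length, soft repulsion on any overlapping pair, Brownian
#' displacement for CTL in SEARCH or DISABLED mode, and a radial clamp at the
#' well wall. Cell states and the clock are untouched; agent count is
#' conserved.
#'
#' @param well a [make_well()] object.
#' @param params a [simulation_params()] object (its mechanics block is used).
#' @param n_steps number of mechanics steps to take.
#' @return The updated `ctl_well`.
#' @export
step_mechanics <- function(well, params, n_steps = 1) {
  stopifnot(inherits(well, "ctl_well"), inherits(params, "simulation_params"))
  out <- cpp_run(.well_to_cpp(well), .cpp_cfg(params), as.integer(n_steps),
                 0L, TRUE, FALSE, 0L, 0, 0, 0,
                 .next_id(well))
  w <- .well_from_cpp(out$world)
  w$clock_min <- well$clock_min # mechanics-only stepping does not advance biology time
  w
}

.next_id <- function(well) {
  ids <- c(well$targets$id, well$ctls$id, 0L)
  as.integer(max(ids) + 1L)
}

#' Agents within a fixed radius of a position
#'
#' Returns the ids of all agents (targets and CTL) whose center lies within
#' `radius` of `position`; identical to an all-pairs scan.
#'
#' @param well a `ctl_well`.
#' @param position numeric length-2, um.
#' @param radius query radius, um, `>= 0`.
#' @return Integer vector of agent ids, sorted.
#' @export
neighbors_within <- function(well, position, radius) {
  stopifnot(inherits(well, "ctl_well"), length(position) == 2)
  if (radius < 0) stop("neighbors_within: 'radius' must be >= 0")
  x <- c(well$targets$x, well$ctls$x)
  y <- c(well$targets$y, well$ctls$y)
  ids <- c(well$targets$id, well$ctls$id)
  if (length(x) == 0) return(integer(0))
  idx <- cpp_neighbors(x, y, position[1], position[2], radius)
  sort(ids[idx])
}

#' All touching agent pairs
#'
#' Two agents touch when their center distance is at most
#' `(r_i + r_j) * (1 + contact_tol)`.
#'
#' @param well a `ctl_well`.
#' @param contact_tol contact tolerance, fraction of summed radii.
#' @return Data frame with columns `a`, `b` (agent ids, `a < b`).
#' @export
detect_contacts <- function(well, contact_tol = 0.05) {
  stopifnot(inherits(well, "ctl_well"))
  x <- c(well$targets$x, well$ctls$x)
  y <- c(well$targets$y, well$ctls$y)
  r <- c(well$targets$radius, well$ctls$radius)
  ids <- c(well$targets$id, well$ctls$id)
  if (length(x) < 2) return(data.frame(a = integer(0), b = integer(0)))
  m <- cpp_contacts(x, y, r, contact_tol)
  a <- ids[m[, 1]]
  b <- ids[m[, 2]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  out <- data.frame(a = lo, b = hi)
  out[order(out$a, out$b), , drop = FALSE]
}
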