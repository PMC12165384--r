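#' Uniform radial grid
#'
#' Node-centered uniform mesh on `[0, r_max]` with node positions
#' `r_i = i * dr`.  The finite-volume cell around node `i` spans
#' `[r_i - dr/2, r_i + dr/2]` (truncated at the domain ends), so the
#' origin carries a zero-area inner face and the `1/r^2` coordinate
#' singularity never enters the discretization.  `w` holds the true cell
#' volumes `4*pi/3 * (r_out^3 - r_in^3)` used for all volume integrals.
#'
#' @param r_max Domain extent (cm).
#' @param dr Node spacing (cm), default 0.015.
#' @return An object of class `"radial_grid"` with fields `dr`, `r_max`,
#'   `r` (node positions) and `w` (cell volumes, cm^3).
#' @export
radial_grid <- function(r_max, dr = 0.015) {
  stopifnot(dr > 0, r_max > dr)
  n <- ceiling(r_max / dr)
  r <- seq(0, by = dr, length.out = n + 1L)
  rin <- pmax(r - dr / 2, 0)
  rout <- pmin(r + dr / 2, r[n + 1L])
  w <- 4 * pi / 3 * (rout^3 - rin^3)
  structure(list(dr = dr, r_max = r[n + 1L], r = r, w = w),
            class = "radial_grid")
}

#' Build a grid sized for a growth run
#'
#' Chooses the domain extent so that the tumor stays well away from the
#' outer boundary over the planned horizon: initial radius plus a
#' Fisher-front travel bound `2*sqrt(a*D_T)*horizon`, plus an allowance
#' for the sub-detectable halo that thresholded diffusion produces ahead
#' of the detectable front, plus a 1 cm buffer.
#'
#' @param initial_radius Initial tumor radius (cm).
#' @param horizon Planned simulation length (days).
#' @param tp A [tumor_params()] object.
#' @param det A [detection_config()]; used for the halo allowance.
#' @param dr Node spacing (cm).
#' @return A [radial_grid()].
#' @export
build_grid <- function(initial_radius, horizon, tp,
                       det = detection_config(), dr = 0.015) {
  stopifnot(initial_radius > 0, horizon >= 0)
  speed <- 2 * sqrt(tp$a * tp$D_T)
  # cells crossing the threshold need ~log(u_detect/u_star)/a days to grow
  # to detectability; the front travels that much further undetected
  halo <- speed * max(log(det$u_detect / tp$u_star), 0) / tp$a
  radial_grid(initial_radius + speed * horizon + halo + 1, dr = dr)
}

#' Simulation state on a radial grid
#'
#' @param u Tumor density per node (cells/cm^3).
#' @param v Effector CAR T-cell density per node (cells/cm^3).
#' @param V_E Exhausted CAR T-cell count (cells), default 0.
#' @param t Current time (days), default 0.
#' @param grid The [radial_grid()] the fields live on.
#' @return An object of class `"state_field"`.
#' @export
state_field <- function(u, v, V_E = 0, t = 0, grid) {
  stopifnot(inherits(grid, "radial_grid"),
            length(u) == length(grid$r), length(v) == length(grid$r))
  if (any(u < 0) || any(v < 0) || V_E < 0)
    stop("state densities and counts must be nonnegative")
  structure(list(u = u, v = v, V_E = V_E, t = t, grid = grid),
            class = "state_field")
}

#' Total cell counts of a state
#'
#' Volume-integrates the density fields: `4*pi * integral(x r^2 dr)` via
#' the grid's finite-volume weights.
#'
#' @param state A [state_field()].
#' @return Named list: `tumor`, `effector`, `exhausted`, `cart_total`.
#' @export
state_totals <- function(state) {
  stopifnot(inherits(state, "state_field"))
  w <- state$grid$w
  eff <- sum(state$v * w)
  list(tumor = sum(state$u * w), effector = eff,
       exhausted = state$V_E, cart_total = eff + state$V_E)
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("radial_grid: %d nodes, dr=%g cm, r_max=%g cm\n",
              length(x$r), x$dr, x$r_max))
  invisible(x)
}

#' @export
print.state_field <- function(x, ...) {
  tot <- state_totals(x)
  cat(sprintf(
    "state_field @ t=%.3f d: %.3g tumor cells, %.3g effector + %.3g exhausted CAR T cells\n",
    x$t, tot$tumor, tot$effector, tot$exhausted))
  invisible(x)
}
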