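#' Solver settings
#'
#' @param dt Time step (days), or `NULL` to use the automatic rule
#'   [dt_rule()] `min(a*dr/D_C, dr/5)`.
#' @param record_every Cadence of the scalar output series (days).
#' @param snapshot_every Cadence of full-field snapshots (days), or `NULL`
#'   for none (the final state is always kept).
#' @param reaction_order 2 for Heun (trapezoidal) treatment of the
#'   reaction terms around the Crank-Nicolson diffusion solve (default),
#'   1 for a single explicit evaluation.
#' @param mask_rule How the thresholded tumor diffusivity is evaluated on
#'   cell faces from the lagged (beginning-of-step) state: `"node"`
#'   (default) averages the two node diffusivities, so an above-threshold
#'   node always leaks outward at half diffusivity; `"face"` applies the
#'   threshold to the face-averaged density, which freezes the front
#'   whenever `u_star` exceeds half the interior density (e.g. a
#'   threshold at 50% of carrying capacity) and is provided for
#'   comparison only.
#' @param stop_tumor_below Early-stop when total tumor cells fall below
#'   this count (0 disables).  Eradication is conventionally `< 1` cell.
#' @param stop_radius_above Early-stop when the detectable radius (cm)
#'   reaches this value (0 disables).
#' @param margin_cm The run is flagged if tumor cells appear within this
#'   distance of the domain edge.
#' @param stop_on_margin Stop (rather than just flag) on margin violation.
#' @return An object of class `"solver_config"`.
#' @export
solver_config <- function(dt = NULL, record_every = 0.25,
                          snapshot_every = NULL, reaction_order = 2,
                          mask_rule = c("node", "face", "either", "ramp"),
                          stop_tumor_below = 0, stop_radius_above = 0,
                          margin_cm = 1, stop_on_margin = FALSE) {
  mask_rule <- match.arg(mask_rule)
  stopifnot(is.null(dt) || dt > 0, record_every > 0,
            reaction_order %in% c(1, 2))
  structure(list(dt = dt, record_every = record_every,
                 snapshot_every = snapshot_every,
                 reaction_order = reaction_order, mask_rule = mask_rule,
                 stop_tumor_below = stop_tumor_below,
                 stop_radius_above = stop_radius_above,
                 margin_cm = margin_cm,
                 stop_on_margin = isTRUE(stop_on_margin)),
            class = "solver_config")
}

#' Automatic time-step rule
#'
#' `dt = min(a * dr / D_C, dr / 5)` days.  This empirical recipe ties the
#' step to the grid spacing and the two transport scales; it is offered
#' verbatim (its dimensional form is unusual) and any explicit `dt`
#' overrides it.
#'
#' @param tp,cp Parameter objects.
#' @param dr Grid spacing (cm).
#' @return Time step (days).
#' @export
dt_rule <- function(tp, cp, dr = 0.015) {
  cand <- if (cp$D_C > 0) tp$a * dr / cp$D_C else Inf
  min(cand, dr / 5)
}

.cart_null <- function() {
  cart_params(D_C = 0, d = 0, s = 1, l = 1, j = 0, k = 1, m = 0, q = 0)
}

.par_list <- function(tp, cp) {
  list(a = tp$a, b = tp$b, D_T = tp$D_T, u_star = tp$u_star,
       D_C = cp$D_C, d = cp$d, s = cp$s, l = cp$l, j = cp$j, k = cp$k,
       m = cp$m, q = cp$q)
}

#' Advance the state by one Crank-Nicolson step
#'
#' Mostly useful for testing and for verification studies; production runs
#' go through [simulate()], which loops in compiled code.
#'
#' @param state A [state_field()].
#' @param tp,cp Parameter objects (`cp = NULL` for a tumor-only system).
#' @param dt Time step (days).
#' @param control A [solver_config()].
#' @return The advanced [state_field()].
#' @export
cn_step <- function(state, tp, cp = NULL, dt, control = solver_config()) {
  stopifnot(inherits(state, "state_field"), dt > 0)
  if (is.null(cp)) cp <- .cart_null()
  res <- cpp_cn_step(state$u, state$v, state$V_E, state$grid$dr, dt,
                     .par_list(tp, cp), control$reaction_order,
                     match(control$mask_rule, c("face", "node", "either", "ramp")) - 1L,
                     1L, 0.0, NULL, NULL)
  state_field(res$u, res$v, res$V_E, state$t + dt, state$grid)
}

#' Simulate the tumor / CAR T-cell system
#'
#' Integrates the coupled radial PDEs plus the exhausted-cell ODE from
#' `state` over `horizon` days, recording a scalar time series (total
#' tumor cells, effector and exhausted CAR T-cell counts, detectable
#' radius and detectable burden) and, optionally, full field snapshots.
#'
#' @param state Initial [state_field()].
#' @param tp A [tumor_params()] object.
#' @param cp A [cart_params()] object, or `NULL` for untreated growth.
#' @param horizon Simulation length (days).
#' @param det A [detection_config()].
#' @param control A [solver_config()].
#' @return A `cart_trajectory`: list with `series` (data frame), `state`
#'   (final [state_field()]), `snapshots`, `stop_reason` (`"horizon"`,
#'   `"eradication"`, `"radius_target"` or `"margin"`), `margin_hit`,
#'   `clamped_mass`, and the run settings.
#' @export
simulate <- function(state, tp, cp = NULL, horizon, det = detection_config(),
                     control = solver_config()) {
  stopifnot(inherits(state, "state_field"), horizon >= 0)
  cp_eff <- if (is.null(cp)) .cart_null() else cp
  dt <- if (is.null(control$dt)) dt_rule(tp, cp_eff, state$grid$dr) else control$dt
  nsteps <- ceiling(horizon / dt)
  if (nsteps == 0L) {
    tot <- state_totals(state)
    series <- data.frame(t = state$t, tumor = tot$tumor,
                         effector = tot$effector, exhausted = tot$exhausted,
                         r_detect = detectable_radius(state, det),
                         detectable = NA_real_, clamped = 0)
    return(structure(list(series = series, state = state, snapshots = NULL,
                          stop_reason = "horizon", margin_hit = FALSE,
                          clamped_mass = 0, dt = dt, tp = tp, cp = cp,
                          det = det, control = control),
                     class = "cart_trajectory"))
  }
  rec_steps <- max(1L, round(control$record_every / dt))
  snap_steps <- if (is.null(control$snapshot_every)) 0L else
    max(1L, round(control$snapshot_every / dt))
  res <- cpp_cn_run(state$u, state$v, state$V_E, state$t, state$grid$dr, dt,
                    as.integer(nsteps), .par_list(tp, cp_eff), det$u_detect,
                    as.integer(rec_steps), as.integer(snap_steps),
                    control$reaction_order,
                    match(control$mask_rule, c("face", "node", "either", "ramp")) - 1L,
                    control$stop_tumor_below, control$stop_radius_above,
                    control$margin_cm, as.integer(control$stop_on_margin))
  series <- as.data.frame(res$series)
  final <- state_field(res$u, res$v, res$V_E, res$t, state$grid)
  structure(list(series = series, state = final, snapshots = res$snapshots,
                 stop_reason = c("horizon", "eradication", "radius_target",
                                 "margin")[res$stop_code + 1L],
                 margin_hit = res$margin_hit > 0,
                 clamped_mass = res$clamped_mass, dt = dt, tp = tp, cp = cp,
                 det = det, control = control),
            class = "cart_trajectory")
}

#' @export
print.cart_trajectory <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf(
    "cart_trajectory: t in [%.2f, %.2f] d (%d records), stop: %s\n",
    x$series$t[1], x$series$t[n], n, x$stop_reason))
  cat(sprintf("  final: %.3g tumor cells, detectable radius %.3f cm\n",
              x$series$tumor[n], x$series$r_detect[n]))
  invisible(x)
}

#' Export a trajectory to CSV files plus a JSON run manifest
#'
#' Writes `<prefix>_series.csv` (scalar time series),
#' `<prefix>_fields.csv` (tidy long-form `time, r, u, v` snapshots, if
#' recorded) and `<prefix>_manifest.json` (all parameters, grid, solver
#' settings) into `dir`.
#'
#' @param traj A `cart_trajectory` from [simulate()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param seed Optional seed to record in the manifest.
#' @return Named character vector of the files written, invisibly.
#' @export
export_trajectory <- function(traj, dir, prefix = "run", seed = NULL) {
  stopifnot(inherits(traj, "cart_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(series = file.path(dir, paste0(prefix, "_series.csv")))
  write.csv(traj$series, files[["series"]], row.names = FALSE)
  if (!is.null(traj$snapshots)) {
    sn <- traj$snapshots
    long <- do.call(rbind, lapply(seq_along(sn$t), function(i) {
      data.frame(time = sn$t[i], r = traj$state$grid$r,
                 u = sn$u[, i], v = sn$v[, i])
    }))
    files <- c(files, fields = file.path(dir, paste0(prefix, "_fields.csv")))
    write.csv(long, files[["fields"]], row.names = FALSE)
  }
  manifest <- list(
    package = "cartloco",
    version = as.character(utils::packageVersion("cartloco")),
    tumor = unclass(traj$tp),
    cart = if (is.null(traj$cp)) NULL else unclass(traj$cp),
    detection = unclass(traj$det),
    grid = list(dr = traj$state$grid$dr, r_max = traj$state$grid$r_max),
    solver = traj$control[!vapply(traj$control, is.null, logical(1))],
    dt = traj$dt, stop_reason = traj$stop_reason,
    margin_hit = traj$margin_hit, clamped_mass = traj$clamped_mass,
    seed = seed)
  files <- c(files, manifest = file.path(dir, paste0(prefix, "_manifest.json")))
  jsonlite::write_json(manifest, files[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(files)
}
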