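#' Grow a tumor to a target detectable radius
#'
#' Starts from a 1 mm radius sphere at uniform carrying-capacity density
#' (sharp edge; the threshold dynamics regularize it within a few steps)
#' and integrates the untreated model until the detectable radius reaches
#' `target_radius`.  The domain is extended automatically if the tumor
#' approaches its edge.  Results are memoized per session, since every
#' outcome-map cell and treatment scenario reuses the same baseline
#' profile.
#'
#' @param tp A [tumor_params()] object.
#' @param target_radius Target detectable radius (cm), >= 0.1.
#' @param det A [detection_config()].
#' @param dr Grid spacing (cm).
#' @param seed_radius Radius of the initial uniform sphere (cm).
#' @param max_days Growth-time cap; exceeded target is an error.
#' @param growth_margin Extra domain allowance (cm) beyond the target for
#'   the post-treatment phase, so downstream simulations need not regrid.
#' @return A [state_field()] at `t = 0` with attribute `"growth_days"`
#'   recording the elapsed growth time.
#' @export
grow_to_size <- function(tp, target_radius, det = detection_config(),
                         dr = 0.015, seed_radius = 0.1, max_days = 3000,
                         growth_margin = 1.5) {
  stopifnot(target_radius >= seed_radius)
  key <- paste(signif(c(tp$a, tp$b, tp$D_T, tp$u_star, det$u_detect,
                        target_radius, dr, seed_radius, growth_margin), 12),
               collapse = "|")
  if (!is.null(.cartloco_cache[[key]])) return(.cartloco_cache[[key]])

  halo <- 2 * sqrt(tp$a * tp$D_T) *
    max(log(det$u_detect / tp$u_star), 0) / tp$a
  grid <- radial_grid(target_radius + halo + growth_margin + 1, dr = dr)
  u <- ifelse(grid$r <= seed_radius, 1 / tp$b, 0)
  st <- state_field(u, rep(0, length(u)), 0, 0, grid)
  if (detectable_radius(st, det) >= target_radius) {
    attr(st, "growth_days") <- 0
    .cartloco_cache[[key]] <- st
    return(st)
  }

  elapsed <- 0
  ctrl <- solver_config(record_every = 1, stop_radius_above = target_radius,
                        stop_on_margin = TRUE)
  repeat {
    tr <- simulate(st, tp, NULL, horizon = max_days - elapsed, det = det,
                   control = ctrl)
    elapsed <- tr$state$t
    if (tr$stop_reason == "radius_target") {
      st <- tr$state
      break
    }
    if (tr$stop_reason == "margin") {
      # pad the domain with empty space and continue
      grid2 <- radial_grid(tr$state$grid$r_max + 1.5, dr = dr)
      pad <- length(grid2$r) - length(tr$state$grid$r)
      st <- state_field(c(tr$state$u, rep(0, pad)),
                        c(tr$state$v, rep(0, pad)),
                        tr$state$V_E, tr$state$t, grid2)
      next
    }
    stop(sprintf(
      "target detectable radius %.3f cm not reached within %g days",
      target_radius, max_days))
  }
  out <- state_field(st$u, st$v, 0, 0, st$grid)
  attr(out, "growth_days") <- elapsed
  .cartloco_cache[[key]] <- out
  out
}

#' Initialize an intratumoral CAR T-cell injection
#'
#' Places the effector fraction of the dose uniformly inside a small ball
#' of radius `r_inj` at the tumor center; the exhausted fraction goes
#' straight into the exhausted count `V_E`.  The tumor field is untouched.
#'
#' @param tumor_state Baseline [state_field()] (e.g. from
#'   [grow_to_size()]).
#' @param dose Total injected CAR T cells.
#' @param exhausted_fraction Fraction of the dose exhausted ex vivo,
#'   in `[0, 1]`.
#' @param r_inj Injection ball radius (cm).  The default (0.5 cm) is a
#'   package choice -- "a high concentration at the center" is inherently
#'   qualitative -- and is recorded in run manifests.
#' @param det A [detection_config()] used only to validate that the
#'   injection sits inside the detectable tumor.
#' @return A [state_field()] with the injection applied.
#' @export
init_intratumoral <- function(tumor_state, dose, exhausted_fraction = 0,
                              r_inj = 0.5, det = detection_config()) {
  stopifnot(inherits(tumor_state, "state_field"))
  if (dose < 0) stop("dose must be nonnegative")
  if (exhausted_fraction < 0 || exhausted_fraction > 1)
    stop("exhausted_fraction must lie in [0, 1]")
  rd <- detectable_radius(tumor_state, det)
  if (dose > 0 && rd > 0 && r_inj >= rd)
    stop("injection radius must be smaller than the detectable tumor radius")
  grid <- tumor_state$grid
  inside <- grid$r <= r_inj
  vol <- sum(grid$w[inside])
  v <- tumor_state$v
  v[inside] <- v[inside] + (1 - exhausted_fraction) * dose / vol
  state_field(tumor_state$u, v,
              tumor_state$V_E + exhausted_fraction * dose,
              tumor_state$t, grid)
}

#' Initialize an intracavitary CAR T-cell administration
#'
#' Places the effector fraction of the dose as a thin uniform shell of
#' thickness `w` on the detectable tumor surface, emulating delivery into
#' the cavity surrounding the tumor; the exhausted fraction goes into
#' `V_E`.
#'
#' @inheritParams init_intratumoral
#' @param w Shell thickness (cm); default two grid cells.
#' @param dr Grid spacing, used only for the default `w`.
#' @return A [state_field()] with the injection applied.
#' @export
init_intracavitary <- function(tumor_state, dose, exhausted_fraction = 0,
                               w = NULL, det = detection_config(),
                               dr = tumor_state$grid$dr) {
  stopifnot(inherits(tumor_state, "state_field"))
  if (dose < 0) stop("dose must be nonnegative")
  if (exhausted_fraction < 0 || exhausted_fraction > 1)
    stop("exhausted_fraction must lie in [0, 1]")
  if (is.null(w)) w <- 2 * dr
  if (w <= 0) stop("shell thickness must be positive")
  grid <- tumor_state$grid
  rd <- detectable_radius(tumor_state, det)
  if (rd + w > grid$r_max)
    stop("shell extends beyond the computational domain")
  shell <- grid$r > rd & grid$r <= rd + w
  if (!any(shell)) shell <- which.min(abs(grid$r - (rd + w / 2)))
  vol <- sum(grid$w[shell])
  v <- tumor_state$v
  v[shell] <- v[shell] + (1 - exhausted_fraction) * dose / vol
  state_field(tumor_state$u, v,
              tumor_state$V_E + exhausted_fraction * dose,
              tumor_state$t, grid)
}

#' Treatment scenario description
#'
#' Bundles everything needed for one treatment run: tumor type, CAR T-cell
#' parameters, delivery mode, dose, ex vivo exhausted fraction, tumor size
#' at treatment and simulation horizon.
#'
#' @param tumor A [tumor_params()] object or a preset name
#'   (`"typeI"`..`"typeIV"`).
#' @param cart A [cart_params()] object or a [cart_preset()] name.
#' @param mode `"intratumoral"`, `"intracavitary"` or `"none"`.
#' @param dose Total injected CAR T cells.
#' @param exhausted_fraction Fraction of the dose exhausted ex vivo.
#' @param treat_diameter Detectable tumor diameter at treatment (cm).
#' @param r_inj Injection ball radius (cm, intratumoral mode).
#' @param shell_w Shell thickness (cm, intracavitary mode); `NULL` for the
#'   grid default.
#' @param horizon Post-treatment simulation length (days).
#' @param det A [detection_config()].
#' @return An object of class `"scenario"`.
#' @export
scenario <- function(tumor, cart = cart_preset("default"),
                     mode = c("intratumoral", "intracavitary", "none"),
                     dose = 0, exhausted_fraction = 0, treat_diameter = 2,
                     r_inj = 0.5, shell_w = NULL, horizon = 56,
                     det = detection_config()) {
  mode <- match.arg(mode)
  if (is.character(tumor)) tumor <- tumor_preset(tumor)
  if (is.character(cart)) cart <- cart_preset(cart)
  stopifnot(inherits(tumor, "tumor_params"), inherits(cart, "cart_params"))
  if (dose < 0) stop("dose must be nonnegative")
  if (exhausted_fraction < 0 || exhausted_fraction > 1)
    stop("exhausted_fraction must lie in [0, 1]")
  structure(list(tumor = tumor, cart = cart, mode = mode, dose = dose,
                 exhausted_fraction = exhausted_fraction,
                 treat_diameter = treat_diameter, r_inj = r_inj,
                 shell_w = shell_w, horizon = horizon, det = det),
            class = "scenario")
}

#' Build the initial state of a scenario
#'
#' Grows the baseline tumor to the treatment size and applies the
#' injection geometry.
#'
#' @param sc A [scenario()].
#' @param dr Grid spacing (cm).
#' @return A [state_field()] ready for [simulate()].
#' @export
scenario_state <- function(sc, dr = 0.015) {
  stopifnot(inherits(sc, "scenario"))
  st <- grow_to_size(sc$tumor, sc$treat_diameter / 2, det = sc$det, dr = dr)
  if (sc$mode == "none" || sc$dose == 0) return(st)
  switch(sc$mode,
    intratumoral = init_intratumoral(st, sc$dose, sc$exhausted_fraction,
                                     r_inj = sc$r_inj, det = sc$det),
    intracavitary = init_intracavitary(st, sc$dose, sc$exhausted_fraction,
                                       w = sc$shell_w, det = sc$det))
}

#' Run a scenario end to end
#'
#' @param sc A [scenario()].
#' @param dr Grid spacing (cm).
#' @param control A [solver_config()]; eradication early-stop is enabled
#'   by default.
#' @return A `cart_trajectory` (see [simulate()]) with the scenario
#'   attached as attribute `"scenario"`.
#' @export
run_scenario <- function(sc, dr = 0.015,
                         control = solver_config(stop_tumor_below = 1)) {
  st <- scenario_state(sc, dr = dr)
  tr <- simulate(st, sc$tumor, if (sc$mode == "none") NULL else sc$cart,
                 horizon = sc$horizon, det = sc$det, control = control)
  attr(tr, "scenario") <- sc
  tr
}
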