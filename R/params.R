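#' Tumor growth parameters
#'
#' Parameters of the logistic growth / thresholded diffusion law for the
#' tumor cell density \eqn{u(r,t)}:
#' \deqn{\partial_t u = \nabla\cdot(D_T(u)\nabla u) + a u (1 - b u) - D(u,v),}
#' where \eqn{D_T(u) = D_T^*} when \eqn{u > u^*} and 0 otherwise
#' ("go-or-grow": below the critical density cells proliferate in place,
#' above it they also migrate), and \eqn{D(u,v)} is the lysis rate
#' ([lysis_rate()]).
#'
#' @param a Tumor proliferation rate (1/day).
#' @param D_T Tumor diffusion constant above threshold (cm^2/day).
#' @param u_star Diffusion threshold density (cells/cm^3).
#' @param b Inverse carrying capacity (cm^3/cell).  The default corresponds
#'   to a local carrying capacity of 2.39e8 cells/cm^3 (10 um cell radius).
#'
#' @return An object of class `"tumor_params"`.
#' @seealso [tumor_preset()] for the four canonical tumor types.
#' @export
#' @examples
#' tp <- tumor_params(a = 0.25, D_T = 1e-5, u_star = 1.2e8)
tumor_params <- function(a, D_T, u_star, b = 1 / 2.39e8) {
  stopifnot(is.numeric(a), is.numeric(D_T), is.numeric(u_star), is.numeric(b))
  if (a <= 0 || D_T <= 0 || u_star <= 0 || b <= 0)
    stop("tumor parameters must be strictly positive")
  if (u_star > 1 / b)
    stop("diffusion threshold u_star exceeds the carrying capacity 1/b")
  structure(list(a = a, b = b, D_T = D_T, u_star = u_star),
            class = "tumor_params")
}

#' Canonical tumor-type parameter presets
#'
#' Four tumor growth archetypes spanning compact/slow-spreading to
#' aggressive/diffuse phenotypes.  All share carrying capacity
#' 1/b = 2.39e8 cells/cm^3; the diffusion threshold is 50%, 10%, 1% and 1%
#' of carrying capacity for types I-IV respectively.
#'
#' \describe{
#'   \item{typeI}{a = 0.25/day, D_T = 1e-5 cm^2/day, u* = 1.2e8 -- compact,
#'     dense tumor (e.g. some liver/breast cancers).}
#'   \item{typeII}{a = 0.125/day, D_T = 2e-5, u* = 2.39e7 -- moderately
#'     aggressive.}
#'   \item{typeIII}{a = 0.025/day, D_T = 1e-4, u* = 2.39e6 -- invasive,
#'     low-density growth front (glioma-like).}
#'   \item{typeIV}{a = 0.25/day, D_T = 1e-4, u* = 2.39e6 -- aggressive and
#'     diffuse.}
#' }
#'
#' @param type One of `"typeI"`, `"typeII"`, `"typeIII"`, `"typeIV"`.
#' @return A [tumor_params()] object.
#' @export
tumor_preset <- function(type = c("typeI", "typeII", "typeIII", "typeIV")) {
  type <- match.arg(type)
  switch(type,
    typeI   = tumor_params(a = 0.25,  D_T = 1e-5, u_star = 1.2e8),
    typeII  = tumor_params(a = 0.125, D_T = 2e-5, u_star = 2.39e7),
    typeIII = tumor_params(a = 0.025, D_T = 1e-4, u_star = 2.39e6),
    typeIV  = tumor_params(a = 0.25,  D_T = 1e-4, u_star = 2.39e6))
}

#' CAR T-cell parameters
#'
#' Kinetic parameters of the effector CAR T-cell density \eqn{v(r,t)}:
#' \deqn{\partial_t v = D_C \nabla^2 v
#'       + j\frac{D^2}{k + D^2}v - m v - q u v,}
#' with \eqn{D = D(u,v)} the lysis rate.  Proliferation is driven by
#' feedback from tumor-cell lysis and saturates at rate `j`; cells die at
#' rate `m` and convert to an exhausted (inactive) state at mass-action
#' rate `q` upon repeated tumor engagement.
#'
#' @param D_C CAR T-cell diffusion constant (cm^2/day).  Default 0.0138,
#'   derived from intratumoral CAR T-cell velocities in murine imaging
#'   studies.  (A value of 1.38 also circulates for the same measurement;
#'   it is interpretable as a unit slip -- use the `D_C` argument to
#'   override if desired.)
#' @param d Maximal lysis rate (1/day).
#' @param s Half-saturation constant for the killing ratio term
#'   \eqn{(v/u)^l} (dimensionless).
#' @param l Killing cooperativity exponent (dimensionless, >= 1).
#' @param j Maximal CAR T-cell proliferation rate (1/day).
#' @param k Half-saturation constant for the squared lysis-rate density
#'   ((cells cm^-3 day^-1)^2).
#' @param m Death rate (1/day).
#' @param q Exhaustion rate constant (cm^3/cell/day).
#' @return An object of class `"cart_params"`.
#' @seealso [cart_preset()]
#' @export
cart_params <- function(D_C = 0.0138, d, s, l, j, k, m, q) {
  vals <- c(D_C = D_C, d = d, s = s, l = l, j = j, k = k, m = m, q = q)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("CAR T-cell parameters must be finite and nonnegative")
  if (l < 1) stop("killing cooperativity exponent l must be >= 1")
  structure(as.list(vals), class = "cart_params")
}

#' CAR T-cell parameter presets
#'
#' Named CAR T-cell kinetic parameter sets used by the shipped scenarios.
#' The source studies report these values only in supplementary tables that
#' are not redistributed here, so each preset is a *synthetic
#' reconstruction*: a parameter vector in the biologically reported ranges
#' (maximal lysis rate of order 1/day, death rate ~0.1-0.4/day, exhaustion
#' ~1e-9 cm^3/cell/day) calibrated so that the shipped scenarios reproduce
#' the qualitative and quantitative treatment behaviors described in the
#' documentation.  See the methods vignette for the calibration rationale.
#'
#' \describe{
#'   \item{default}{Human-tumor simulations (outcome maps, sensitivity
#'     sweeps, worked treatment examples).}
#'   \item{zhao}{Mouse-scale intratumoral injection fit (flank
#'     mesothelioma, single 1e7-cell dose).}
#'   \item{skovgard}{Mouse-scale intrapleural (intracavitary)
#'     injection fit (orthotopic mesothelioma, single 1e7-cell dose).}
#' }
#'
#' @param name Preset name.
#' @return A [cart_params()] object.
#' @export
cart_preset <- function(name = c("default", "zhao", "skovgard")) {
  name <- match.arg(name)
  switch(name,
    default = cart_params(D_C = 0.0138, d = 0.9, s = 1.5, l = 2,
                          j = 3, k = 4e15, m = 0.35, q = 6e-9),
    zhao = cart_params(D_C = 0.0138, d = 2.9, s = 1.5, l = 2,
                       j = 3, k = 4e15, m = 0.35, q = 6e-9),
    skovgard = cart_params(D_C = 0.0138, d = 6.0, s = 1.5, l = 2,
                           j = 7, k = 4e15, m = 0.35, q = 6e-9))
}

#' Imaging detection threshold
#'
#' @param u_detect Detection threshold density (cells/cm^3); tumor tissue
#'   below this density is invisible to imaging.  Default 1e8 (~40% of the
#'   default carrying capacity).
#' @param b Inverse carrying capacity, used only for validation.
#' @return An object of class `"detection_config"`.
#' @export
detection_config <- function(u_detect = 1e8, b = 1 / 2.39e8) {
  if (u_detect <= 0 || u_detect > 1 / b)
    stop("u_detect must lie in (0, 1/b]")
  structure(list(u_detect = u_detect), class = "detection_config")
}

# density floor used inside the v/u ratio only, to avoid overflow;
# has no effect at physical densities
.EPS_DENSITY <- 1e-12

#' Ratio-dependent tumor lysis rate
#'
#' The local rate at which CAR T cells kill tumor cells,
#' \deqn{D(u,v) = d\,\frac{(v/u)^l}{s + (v/u)^l}\,u,}
#' saturating in the CAR T : tumor density ratio (de Pillis-type fractional
#' kill).  By convention the rate is 0 when `u = 0` (nothing to kill) or
#' `v = 0` (no killers); for small positive `u` the Hill term saturates and
#' the rate tends to \eqn{d\,u}.
#'
#' @param u Tumor density (cells/cm^3), scalar or vector.
#' @param v Effector CAR T-cell density (cells/cm^3), same length.
#' @param p A [cart_params()] object.
#' @param eps Density floor used inside the ratio to avoid division
#'   overflow; default 1e-12 cells/cm^3.
#' @return Lysis rate density (cells cm^-3 day^-1), in `[0, d*u]`.
#' @export
#' @examples
#' p <- cart_params(d = 0.45, s = 1, l = 1, j = 1, k = 1, m = 0.1, q = 0)
#' lysis_rate(1e6, 1e6, p)  # = 0.45 * 0.5 * 1e6
lysis_rate <- function(u, v, p, eps = .EPS_DENSITY) {
  stopifnot(inherits(p, "cart_params"))
  if (any(u < 0) || any(v < 0)) stop("densities must be nonnegative")
  ratio <- (v / pmax(u, eps))^p$l
  out <- p$d * ratio / (p$s + ratio) * u
  out[u == 0 | v == 0] <- 0
  out
}

#' Net tumor reaction rate
#'
#' Logistic growth minus CAR T-cell lysis:
#' \eqn{F_1(u,v) = a u (1 - b u) - D(u,v)}.
#'
#' @inheritParams lysis_rate
#' @param tp A [tumor_params()] object.
#' @param cp A [cart_params()] object.
#' @return Net tumor rate (cells cm^-3 day^-1).
#' @export
tumor_forcing <- function(u, v, tp, cp) {
  stopifnot(inherits(tp, "tumor_params"))
  if (any(u < 0) || any(v < 0)) stop("densities must be nonnegative")
  tp$a * u * (1 - tp$b * u) - lysis_rate(u, v, cp)
}

#' Net effector CAR T-cell reaction rate
#'
#' Lysis-driven saturating proliferation minus death and exhaustion:
#' \eqn{F_2(u,v) = j D^2/(k + D^2)\,v - m v - q u v} with
#' \eqn{D = D(u,v)} from [lysis_rate()].
#'
#' @inheritParams lysis_rate
#' @param cp A [cart_params()] object.
#' @return Net effector rate (cells cm^-3 day^-1).
#' @export
cart_forcing <- function(u, v, cp) {
  if (any(u < 0) || any(v < 0)) stop("densities must be nonnegative")
  D <- lysis_rate(u, v, cp)
  cp$j * D^2 / (cp$k + D^2) * v - cp$m * v - cp$q * u * v
}

#' Exhausted CAR T-cell balance
#'
#' The exhausted compartment is a whole-tumor count \eqn{V_E(t)} obeying
#' \deqn{dV_E/dt = -m V_E + 4\pi q \int_0^{r_{max}} u v r^2\,dr,}
#' i.e. exponential clearance at the effector death rate plus the
#' volume-integrated exhaustion influx.
#'
#' @param state A `state_field` (see [state_field()]).
#' @param cp A [cart_params()] object.
#' @param grid A [radial_grid()] object.
#' @return dV_E/dt (cells/day).
#' @export
exhausted_rhs <- function(state, cp, grid) {
  stopifnot(inherits(state, "state_field"), inherits(grid, "radial_grid"))
  influx <- cp$q * sum(state$u * state$v * grid$w)
  -cp$m * state$V_E + influx
}

#' Serialize parameter sets to a configuration file
#'
#' Writes tumor, CAR T and detection parameters as YAML (or JSON) with
#' units embedded in the key names, so configurations are self-describing
#' and silent unit errors are avoided.
#'
#' @param tp,cp Parameter objects; either may be `NULL`.
#' @param det Optional [detection_config()].
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_params <- function(path, tp = NULL, cp = NULL, det = NULL) {
  out <- list()
  if (!is.null(tp)) {
    stopifnot(inherits(tp, "tumor_params"))
    out$tumor <- list(a_per_day = tp$a, b_cm3_per_cell = tp$b,
                      D_T_cm2_per_day = tp$D_T,
                      u_star_cells_per_cm3 = tp$u_star)
  }
  if (!is.null(cp)) {
    stopifnot(inherits(cp, "cart_params"))
    out$cart <- list(D_C_cm2_per_day = cp$D_C, d_per_day = cp$d, s = cp$s,
                     l = cp$l, j_per_day = cp$j,
                     k_lysis_density_sq = cp$k, m_per_day = cp$m,
                     q_cm3_per_cell_per_day = cp$q)
  }
  if (!is.null(det)) {
    stopifnot(inherits(det, "detection_config"))
    out$detection <- list(u_detect_cells_per_cm3 = det$u_detect)
  }
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}

#' Read parameter sets from a configuration file
#'
#' @param path A YAML or JSON file written by [write_params()] (or
#'   hand-authored with the same unit-suffixed keys).
#' @return A list with elements `tumor`, `cart`, `det` (those present).
#' @export
read_params <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- list()
  if (!is.null(raw$tumor)) {
    tt <- raw$tumor
    out$tumor <- tumor_params(a = tt$a_per_day, D_T = tt$D_T_cm2_per_day,
                              u_star = tt$u_star_cells_per_cm3,
                              b = tt$b_cm3_per_cell)
  }
  if (!is.null(raw$cart)) {
    cc <- raw$cart
    out$cart <- cart_params(D_C = cc$D_C_cm2_per_day, d = cc$d_per_day,
                            s = cc$s, l = cc$l, j = cc$j_per_day,
                            k = cc$k_lysis_density_sq, m = cc$m_per_day,
                            q = cc$q_cm3_per_cell_per_day)
  }
  if (!is.null(raw$detection)) {
    out$det <- detection_config(u_detect = raw$detection$u_detect_cells_per_cm3)
  }
  out
}

#' @export
print.tumor_params <- function(x, ...) {
  cat(sprintf(
    "tumor_params: a=%g/day  D_T=%g cm^2/day  u*=%g cells/cm^3  1/b=%g cells/cm^3\n",
    x$a, x$D_T, x$u_star, 1 / x$b))
  invisible(x)
}

#' @export
print.cart_params <- function(x, ...) {
  cat(sprintf(
    "cart_params: D_C=%g cm^2/day  d=%g/day  s=%g  l=%g  j=%g/day  k=%g  m=%g/day  q=%g cm^3/cell/day\n",
    x$D_C, x$d, x$s, x$l, x$j, x$k, x$m, x$q))
  invisible(x)
}
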