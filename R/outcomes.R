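#' Detectable tumor radius
#'
#' The outermost radius at which the tumor density reaches the imaging
#' detection threshold, with linear interpolation between the bracketing
#' grid nodes; 0 if the tumor is nowhere detectable.
#'
#' @param state A [state_field()].
#' @param det A [detection_config()].
#' @return Radius (cm).
#' @export
detectable_radius <- function(state, det = detection_config()) {
  stopifnot(inherits(state, "state_field"))
  u <- state$u
  r <- state$grid$r
  ud <- det$u_detect
  idx <- which(u >= ud)
  if (length(idx) == 0L) return(0)
  i <- max(idx)
  if (i == length(u)) return(r[i])
  frac <- (u[i] - ud) / (u[i] - u[i + 1L])
  r[i] + frac * state$grid$dr
}

#' Tumor burden summaries
#'
#' @param state A [state_field()].
#' @param det A [detection_config()].
#' @return List with `total` (all tumor cells, `4*pi*int u r^2 dr`),
#'   `detectable` (cells within the detectable radius), and
#'   `avg_density` (detectable cells / detectable volume; `NA` when
#'   nothing is detectable).
#' @export
burdens <- function(state, det = detection_config()) {
  stopifnot(inherits(state, "state_field"))
  grid <- state$grid
  total <- sum(state$u * grid$w)
  rd <- detectable_radius(state, det)
  if (rd <= 0)
    return(list(total = total, detectable = 0, avg_density = NA_real_))
  rin <- pmax(grid$r - grid$dr / 2, 0)
  rout <- pmin(grid$r + grid$dr / 2, grid$r_max)
  vin <- 4 * pi / 3 * (pmin(rout, rd)^3 - pmin(rin, rd)^3)
  vin[vin < 0] <- 0
  detc <- sum(state$u * vin)
  list(total = total, detectable = detc,
       avg_density = detc / (4 * pi / 3 * rd^3))
}

# linearly interpolated first crossing time of y >= target
.first_crossing <- function(t, y, target) {
  hit <- which(y >= target)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1L]
  if (i == 1L) return(t[1L])
  t[i - 1L] + (target - y[i - 1L]) / (y[i] - y[i - 1L]) * (t[i] - t[i - 1L])
}

#' Volume doubling time and time to progression
#'
#' Computed from an untreated trajectory whose first record is the
#' baseline (conventionally a 2 cm detectable diameter).  VDT is the first
#' time the detectable tumor volume reaches twice baseline (a diameter
#' factor of 2^(1/3)); TTP is the first time the detectable diameter
#' reaches 1.2x baseline (the progression bound used for solid tumors).
#' Both use linear interpolation between recorded samples.
#'
#' @param traj A `cart_trajectory` from [simulate()].
#' @return List with `vdt` and `ttp` (days since baseline; `NA` with a
#'   `reached` flag when an event lies beyond the trajectory).
#' @export
vdt_ttp <- function(traj) {
  stopifnot(inherits(traj, "cart_trajectory"))
  s <- traj$series
  t <- s$t - s$t[1L]
  vol <- 4 * pi / 3 * s$r_detect^3
  vdt <- .first_crossing(t, vol, 2 * vol[1L])
  ttp <- .first_crossing(t, s$r_detect, 1.2 * s$r_detect[1L])
  list(vdt = vdt, ttp = ttp,
       reached = c(vdt = !is.na(vdt), ttp = !is.na(ttp)))
}

# detectable diameter series of a trajectory, padded with zeros past an
# eradication stop
.diameter_at <- function(traj, times) {
  s <- traj$series
  d <- 2 * s$r_detect
  if (max(times) > max(s$t)) {
    if (traj$stop_reason != "eradication")
      stop("evaluation time lies beyond the simulated horizon")
    s_t <- c(s$t, max(times))
    d <- c(d, 0)
  } else s_t <- s$t
  approx(s_t, d, xout = times, rule = 2)$y
}

#' RECIST response classification
#'
#' Diameter-based solid-tumor response at a follow-up time: complete
#' response (CR) if no measurable lesion remains, partial response (PR) if
#' the diameter decreased by at least 30%, progressive disease (PD) if the
#' diameter increased by at least 20% at or before evaluation (progression
#' is irreversible), stable disease (SD) otherwise.
#'
#' @param baseline_diameter Detectable diameter at treatment (cm).
#' @param traj A `cart_trajectory`.
#' @param eval_time Evaluation time (days after treatment), default 56
#'   (8 weeks).
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
classify_recist <- function(baseline_diameter, traj, eval_time = 56) {
  s <- traj$series
  t0 <- s$t[1L]
  within <- s$t - t0 <= eval_time + 1e-9
  d_path <- 2 * s$r_detect[within]
  if (any(d_path >= 1.2 * baseline_diameter)) return("PD")
  d_eval <- .diameter_at(traj, t0 + eval_time)
  if (d_eval <= 0) return("CR")
  if (d_eval >= 1.2 * baseline_diameter) return("PD")
  if (d_eval <= 0.7 * baseline_diameter) return("PR")
  "SD"
}

#' Choi response classification
#'
#' Accepts either a size or a density criterion for response: partial
#' response if the average detectable tumor density falls to 0.85x
#' baseline or below (a 15% density decrease) or the diameter decreases by
#' at least 10%; complete response as under RECIST; progressive disease if
#' the diameter increases by at least 10% (at or before evaluation) and
#' the density criterion is not met; stable disease otherwise.
#'
#' @inheritParams classify_recist
#' @param baseline_density Average detectable density at treatment
#'   (cells/cm^3); taken from the trajectory's first record if `NULL`.
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
classify_choi <- function(baseline_diameter, traj, eval_time = 56,
                          baseline_density = NULL) {
  s <- traj$series
  t0 <- s$t[1L]
  dens <- ifelse(s$r_detect > 0,
                 s$detectable / (4 * pi / 3 * s$r_detect^3), 0)
  if (is.null(baseline_density)) baseline_density <- dens[1L]
  d_eval <- .diameter_at(traj, t0 + eval_time)
  if (d_eval <= 0) return("CR")
  idx_eval <- max(which(s$t - t0 <= eval_time + 1e-9))
  density_fold <- dens[idx_eval] / baseline_density
  density_pr <- is.finite(density_fold) && density_fold <= 0.85
  size_pr <- d_eval <= 0.9 * baseline_diameter
  within <- s$t - t0 <= eval_time + 1e-9
  progressed <- any(2 * s$r_detect[within] >= 1.1 * baseline_diameter) ||
    d_eval >= 1.1 * baseline_diameter
  if (density_pr || size_pr) return("PR")
  if (progressed) return("PD")
  "SD"
}

#' Trajectory outcome summary
#'
#' @param traj A `cart_trajectory` from a treatment run.
#' @param eval_time Evaluation time (days after treatment).
#' @return A one-row data frame: RECIST and Choi labels, tumor nadir and
#'   its timing, peak total CAR T-cell count, eradication time (`NA` if
#'   the tumor was not eradicated) and baseline diameter.
#' @export
outcome_record <- function(traj, eval_time = 56) {
  s <- traj$series
  t0 <- s$t[1L]
  baseline_diameter <- 2 * s$r_detect[1L]
  post <- s$t > t0  # nadir is sought after the injection
  nadir_idx <- if (any(post)) which(post)[which.min(s$tumor[post])] else 1L
  cart_tot <- s$effector + s$exhausted
  erad <- if (traj$stop_reason == "eradication")
    s$t[nrow(s)] - t0 else NA_real_
  data.frame(
    recist = classify_recist(baseline_diameter, traj, eval_time),
    choi = classify_choi(baseline_diameter, traj, eval_time),
    nadir_cells = s$tumor[nadir_idx], t_nadir = s$t[nadir_idx] - t0,
    peak_cart = max(cart_tot), t_eradication = erad,
    baseline_diameter = baseline_diameter, eval_time = eval_time,
    stringsAsFactors = FALSE)
}

#' Outcome map over dose and exhausted fraction
#'
#' Runs one treatment simulation per (dose, exhausted fraction) grid cell
#' and classifies the outcome under both RECIST and Choi.
#'
#' @param tumor A [tumor_params()] object or preset name.
#' @param mode `"intratumoral"` or `"intracavitary"`.
#' @param doses Vector of total doses (cells).
#' @param exhausted_fractions Vector of ex vivo exhausted fractions in
#'   `[0, 1]`.
#' @param cart A [cart_params()] object or preset name.
#' @param treat_diameter Detectable diameter at treatment (cm).
#' @param eval_time Evaluation time (days).
#' @param horizon Simulation length (days), at least `eval_time`.
#' @param det A [detection_config()].
#' @param dr Grid spacing (cm).
#' @return A data frame of class `"outcome_map"`: one row per grid cell
#'   with dose, exhausted fraction, labels and trajectory summaries.
#'   Individual run failures are recorded as `NA` labels.
#' @export
outcome_map <- function(tumor, mode = c("intratumoral", "intracavitary"),
                        doses = 10^seq(7, 9, length.out = 5),
                        exhausted_fractions = seq(0, 1, by = 0.25),
                        cart = cart_preset("default"), treat_diameter = 2,
                        eval_time = 56, horizon = eval_time,
                        det = detection_config(), dr = 0.015) {
  mode <- match.arg(mode)
  if (is.character(tumor)) tumor <- tumor_preset(tumor)
  if (is.character(cart)) cart <- cart_preset(cart)
  stopifnot(horizon >= eval_time)
  cells <- expand.grid(dose = doses, exhausted_fraction = exhausted_fractions,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sc <- scenario(tumor, cart, mode = mode, dose = cells$dose[i],
                   exhausted_fraction = cells$exhausted_fraction[i],
                   treat_diameter = treat_diameter, horizon = horizon,
                   det = det)
    rec <- tryCatch(outcome_record(run_scenario(sc, dr = dr), eval_time),
                    error = function(e) {
                      warning(sprintf("run (dose=%g, f=%g) failed: %s",
                                      cells$dose[i],
                                      cells$exhausted_fraction[i],
                                      conditionMessage(e)))
                      data.frame(recist = NA_character_,
                                 choi = NA_character_,
                                 nadir_cells = NA_real_, t_nadir = NA_real_,
                                 peak_cart = NA_real_,
                                 t_eradication = NA_real_,
                                 baseline_diameter = NA_real_,
                                 eval_time = eval_time)
                    })
    cbind(cells[i, , drop = FALSE], rec)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("outcome_map", class(out))
  out
}

#' Minimum effective CAR T-cell dose
#'
#' Log-scale bisection for the smallest dose achieving tumor eradication
#' (total tumor cells < 1) within the horizon.
#'
#' @param tumor A [tumor_params()] object or preset name.
#' @param mode Delivery mode.
#' @param cart CAR T-cell parameters or preset name.
#' @param treat_diameter Detectable diameter at treatment (cm).
#' @param horizon Simulation length (days).
#' @param dose_range Bracketing dose range (cells).
#' @param tol_factor Bisection stops when the bracket ratio falls below
#'   this factor (default 1.1).
#' @param exhausted_fraction Ex vivo exhausted fraction of each dose.
#' @param det,dr As elsewhere.
#' @return List with `dose` (cells; 0 if the tumor eradicates untreated,
#'   `NA` if even the top dose fails), `achieved` flag and the number of
#'   simulations used.
#' @export
min_effective_dose <- function(tumor,
                               mode = c("intratumoral", "intracavitary"),
                               cart = cart_preset("default"),
                               treat_diameter = 2, horizon = 56,
                               dose_range = c(1e7, 1e9), tol_factor = 1.1,
                               exhausted_fraction = 0,
                               det = detection_config(), dr = 0.015) {
  mode <- match.arg(mode)
  if (is.character(tumor)) tumor <- tumor_preset(tumor)
  if (is.character(cart)) cart <- cart_preset(cart)
  n_sim <- 0L
  eradicates <- function(dose) {
    sc <- scenario(tumor, cart, mode = mode, dose = dose,
                   exhausted_fraction = exhausted_fraction,
                   treat_diameter = treat_diameter, horizon = horizon,
                   det = det)
    n_sim <<- n_sim + 1L
    run_scenario(sc, dr = dr)$stop_reason == "eradication"
  }
  if (eradicates(0))
    return(list(dose = 0, achieved = TRUE, n_sim = n_sim))
  if (!eradicates(dose_range[2]))
    return(list(dose = NA_real_, achieved = FALSE, n_sim = n_sim))
  if (eradicates(dose_range[1]))
    return(list(dose = dose_range[1], achieved = TRUE, n_sim = n_sim,
                at_lower_bound = TRUE))
  lo <- dose_range[1]  # fails
  hi <- dose_range[2]  # succeeds
  while (hi / lo > tol_factor) {
    mid <- sqrt(lo * hi)
    if (eradicates(mid)) hi <- mid else lo <- mid
  }
  list(dose = hi, achieved = TRUE, n_sim = n_sim)
}

#' Tumor characteristics vs minimum dose sweep
#'
#' For each tumor parameterization (at a fixed detectable diameter at
#' treatment), computes the minimum effective intratumoral dose and four
#' candidate predictors: average detectable density, the ratio a/D_T,
#' total tumor burden, and VDT.
#'
#' @param tumors List of [tumor_params()] objects (>= 3).
#' @param cart CAR T-cell parameters.
#' @param treat_diameter Detectable diameter at treatment (cm).
#' @param horizon Treatment horizon for the dose search (days).
#' @param vdt_horizon Horizon for the untreated VDT run (days).
#' @param dose_range,det,dr As in [min_effective_dose()].
#' @return Data frame with one row per tumor: parameters, predictors and
#'   `min_dose`.
#' @export
predictor_sweep <- function(tumors, cart = cart_preset("default"),
                            treat_diameter = 2, horizon = 56,
                            vdt_horizon = 250, dose_range = c(1e7, 1e9),
                            det = detection_config(), dr = 0.015) {
  rows <- lapply(tumors, function(tp) {
    st <- grow_to_size(tp, treat_diameter / 2, det = det, dr = dr)
    b <- burdens(st, det)
    untreated <- simulate(st, tp, NULL, horizon = vdt_horizon, det = det,
                          control = solver_config(record_every = 1))
    vd <- vdt_ttp(untreated)$vdt
    md <- min_effective_dose(tp, "intratumoral", cart,
                             treat_diameter = treat_diameter,
                             horizon = horizon, dose_range = dose_range,
                             det = det, dr = dr)
    data.frame(a = tp$a, D_T = tp$D_T, u_star = tp$u_star,
               avg_density = b$avg_density, a_over_DT = tp$a / tp$D_T,
               total_burden = b$total, vdt = vd, min_dose = md$dose)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regressions of minimum dose on tumor characteristics
#'
#' Ordinary least squares of log10 minimum effective dose on the log10 of
#' each candidate predictor, reporting R^2 and AIC per predictor.
#'
#' @param data Data frame with a `min_dose` column plus predictor columns
#'   (e.g. from [predictor_sweep()], or synthetic).
#' @param predictors Character vector of predictor column names.
#' @return Data frame with columns `predictor`, `r_squared`, `aic`,
#'   `slope`, ordered by decreasing R^2.
#' @export
dose_predictors <- function(data,
                            predictors = c("avg_density", "a_over_DT",
                                           "total_burden", "vdt")) {
  stopifnot(is.data.frame(data), "min_dose" %in% names(data))
  use <- stats::complete.cases(data[, c("min_dose", predictors)])
  data <- data[use, , drop = FALSE]
  if (nrow(data) < 3) stop("need at least 3 complete tumor parameterizations")
  y <- log10(data$min_dose)
  rows <- lapply(predictors, function(pn) {
    x <- log10(data[[pn]])
    if (length(unique(x)) < 2) stop(sprintf("degenerate predictor '%s'", pn))
    fit <- lm(y ~ x)
    data.frame(predictor = pn, r_squared = summary(fit)$r.squared,
               aic = AIC(fit), slope = unname(coef(fit)[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$r_squared), ]
}

#' One-at-a-time sensitivity sweep
#'
#' Varies one model parameter across a value grid while holding the rest
#' of the base scenario fixed, and records the tumor nadir, its timing,
#' and the peak total CAR T-cell count.  The default base scenario is
#' intratumoral injection of 5e8 effector CAR T cells into a type II tumor
#' followed for 30 days.
#'
#' @param param Parameter name: one of `"D_C"`, `"d"`, `"s"`, `"l"`,
#'   `"j"`, `"k"`, `"m"`, `"q"` (CAR T), or `"a"`, `"D_T"`, `"u_star"`
#'   (tumor).
#' @param values Numeric grid of values to test.
#' @param base A [scenario()]; the default mirrors the standard
#'   sensitivity setup.
#' @param dr Grid spacing (cm).
#' @return Data frame with one row per value: `value`, `nadir`,
#'   `t_nadir`, `peak_cart`, `eradicated`.
#' @export
sensitivity_sweep <- function(param, values,
                              base = scenario("typeII",
                                              cart_preset("default"),
                                              mode = "intratumoral",
                                              dose = 5e8, horizon = 30),
                              dr = 0.015) {
  cart_names <- c("D_C", "d", "s", "l", "j", "k", "m", "q")
  tumor_names <- c("a", "D_T", "u_star")
  if (!param %in% c(cart_names, tumor_names))
    stop(sprintf("unknown parameter '%s'", param))
  rows <- lapply(values, function(val) {
    sc <- base
    if (param %in% cart_names) {
      cp <- unclass(sc$cart)
      cp[[param]] <- val
      sc$cart <- do.call(cart_params, cp)
    } else {
      tp <- unclass(sc$tumor)
      names(tp)[names(tp) == "D_T"] <- "D_T"
      sc$tumor <- tumor_params(a = if (param == "a") val else tp$a,
                               D_T = if (param == "D_T") val else tp$D_T,
                               u_star = if (param == "u_star") val else tp$u_star,
                               b = tp$b)
    }
    tr <- run_scenario(sc, dr = dr)
    rec <- outcome_record(tr, eval_time = min(56, sc$horizon))
    data.frame(value = val, nadir = rec$nadir_cells,
               t_nadir = rec$t_nadir, peak_cart = rec$peak_cart,
               eradicated = !is.na(rec$t_eradication))
  })
  out <- do.call(rbind, rows)
  attr(out, "param") <- param
  out
}

#' Export an outcome map as long-form CSV
#'
#' @param map An `outcome_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcome_map <- function(map, path) {
  stopifnot(inherits(map, "outcome_map"))
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
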