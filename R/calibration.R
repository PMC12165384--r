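#' Longitudinal observation series
#'
#' A time series of tumor-burden or CAR T-cell measurements, as digitized
#' from mouse bioluminescent-imaging (BLI) studies.  BLI signals are
#' proportional to cell number with an unknown scale factor, so series may
#' be marked `scale = "proportional"`; the scale is then profiled out
#' analytically inside the fitting objective.
#'
#' @param times Measurement times (days), strictly increasing.
#' @param values Measurements (cells, or BLI-proportional units), >= 0.
#' @param population `"tumor"` or `"cart"`.
#' @param scale `"absolute"` or `"proportional"`.
#' @return Object of class `"time_series"`.
#' @export
time_series <- function(times, values, population = c("tumor", "cart"),
                        scale = c("absolute", "proportional")) {
  population <- match.arg(population)
  scale <- match.arg(scale)
  stopifnot(length(times) == length(values), length(times) >= 1)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("values must be nonnegative")
  structure(list(times = times, values = values, population = population,
                 scale = scale), class = "time_series")
}

#' Read / write two-column series CSV
#'
#' Plain `time_days,value` CSV with a one-line header.
#'
#' @param path File path.
#' @param population,scale Metadata for the constructed series.
#' @return A [time_series()].
#' @export
read_series_csv <- function(path, population = "tumor", scale = "absolute") {
  d <- read.csv(path)
  time_series(d[[1]], d[[2]], population = population, scale = scale)
}

#' @rdname read_series_csv
#' @param series A [time_series()].
#' @export
write_series_csv <- function(series, path) {
  write.csv(data.frame(time_days = series$times, value = series$values),
            path, row.names = FALSE)
  invisible(path)
}

# model totals at requested times from a trajectory (tumor or total CAR T),
# padding past an eradication stop with the dying-CAR-T tail approximated
# by the final record
.model_at <- function(traj, times, population) {
  s <- traj$series
  y <- if (population == "tumor") s$tumor else s$effector + s$exhausted
  if (max(times) > max(s$t) + 1e-9) {
    if (traj$stop_reason == "eradication" && population == "tumor") {
      s_t <- c(s$t, max(times)); y <- c(y, 0)
    } else if (traj$stop_reason == "eradication") {
      # CAR T cells decay exponentially once the tumor is gone
      m <- if (!is.null(traj$cp)) traj$cp$m else 0
      extra <- times[times > max(s$t)]
      s_t <- c(s$t, extra)
      y <- c(y, y[length(y)] * exp(-m * (extra - max(s$t))))
    } else stop("series times extend beyond the simulated horizon")
  } else s_t <- s$t
  approx(s_t, y, xout = times, rule = 2)$y
}

#' Least-squares objective against observation series
#'
#' Sum of squared residuals between model predictions and one or more
#' [time_series()].  For proportional series the optimal scale factor
#' `alpha = sum(m*d)/sum(m^2)` is profiled out analytically before the
#' residual is formed.  Weights default to equal per series.
#'
#' @param traj A `cart_trajectory` covering the series times (or stopped
#'   by eradication before them).
#' @param series_list List of [time_series()] objects.
#' @param weights Numeric weights, one per series.
#' @return Scalar objective (squared units of the data).
#' @export
objective_sse <- function(traj, series_list, weights = NULL) {
  if (inherits(series_list, "time_series")) series_list <- list(series_list)
  if (is.null(weights)) weights <- rep(1, length(series_list))
  total <- 0
  for (i in seq_along(series_list)) {
    ser <- series_list[[i]]
    m <- .model_at(traj, ser$times, ser$population)
    if (ser$scale == "proportional") {
      denom <- sum(m^2)
      alpha <- if (denom > 0) sum(m * ser$values) / denom else 0
      m <- alpha * m
    }
    total <- total + weights[i] * sum((m - ser$values)^2)
  }
  total
}

#' Fit tumor growth parameters to pre-treatment data
#'
#' Bounded two-parameter least squares for the proliferation rate `a` and
#' diffusion constant `D_T` from an untreated tumor-burden series, with
#' carrying capacity and diffusion threshold held fixed.  The simulation
#' starts from a uniform sphere at carrying capacity.
#'
#' @param series A pre-treatment tumor [time_series()] (>= 2 points).
#' @param b,u_star Fixed inverse carrying capacity and threshold.
#' @param init Named vector with starting values `a`, `D_T`.
#' @param lower,upper Named bounds for `a` and `D_T`.
#' @param seed_radius Initial tumor radius (cm) at the first series time.
#' @param det A [detection_config()].
#' @param dr,dt Solver resolution (mouse-scale default `dr` 0.005 cm).
#' @return List with `par` (named vector `a`, `D_T`), `objective`,
#'   `converged`, and the `optim` diagnostics.
#' @export
fit_growth <- function(series, b = 1 / 2.39e8, u_star = 2.39e6,
                       init = c(a = 0.2, D_T = 5e-5),
                       lower = c(a = 0.01, D_T = 1e-6),
                       upper = c(a = 1, D_T = 1e-3),
                       seed_radius = 0.15, det = detection_config(),
                       dr = 0.005, dt = 0.01) {
  stopifnot(inherits(series, "time_series"))
  if (length(series$times) < 2)
    stop("need at least 2 pre-treatment points to fit growth parameters")
  horizon <- max(series$times) - series$times[1]
  obj <- function(logpar) {
    a <- exp(logpar[1]); D_T <- exp(logpar[2])
    tp <- tumor_params(a = a, D_T = D_T, u_star = u_star, b = b)
    grid <- radial_grid(seed_radius + 2 * sqrt(a * D_T) * horizon + 0.6,
                        dr = dr)
    u0 <- ifelse(grid$r <= seed_radius, 1 / b, 0)
    st <- state_field(u0, rep(0, length(u0)), 0, series$times[1], grid)
    tr <- tryCatch(
      simulate(st, tp, NULL, horizon = horizon, det = det,
               control = solver_config(dt = dt, record_every = 0.5)),
      error = function(e) NULL)
    if (is.null(tr)) return(1e300)
    objective_sse(tr, series)
  }
  fit <- optim(log(init), obj, method = "L-BFGS-B",
               lower = log(lower), upper = log(upper),
               control = list(factr = 1e8))
  list(par = setNames(exp(fit$par), c("a", "D_T")), objective = fit$value,
       converged = fit$convergence == 0, optim = fit)
}

#' Fit the maximal lysis rate to treated data
#'
#' One-dimensional search over `d`: starting from an initial guess, the
#' bracket is expanded upward (the treated data constrain how fast the
#' burden must fall) and the objective minimized by golden-section search.
#'
#' @param series Treated tumor [time_series()] (times measured from
#'   injection).
#' @param sc A [scenario()] describing the treatment run; its `cart$d` is
#'   the initial guess.
#' @param d_max Upper bracket bound for `d` (1/day).
#' @param dr,dt Solver resolution.
#' @return List with `d`, `objective` and the bracket used.
#' @export
fit_killing_rate <- function(series, sc, d_max = 50, dr = 0.005, dt = 0.0025) {
  stopifnot(inherits(series, "time_series"), inherits(sc, "scenario"))
  if (length(series$times) < 1) stop("empty series")
  obj <- function(d) {
    cp <- sc$cart
    cp$d <- d
    sc2 <- sc
    sc2$cart <- cp
    sc2$horizon <- max(sc$horizon, max(series$times))
    tr <- tryCatch(
      run_scenario(sc2, dr = dr,
                   control = solver_config(dt = dt, record_every = 0.5,
                                           stop_tumor_below = 1)),
      error = function(e) NULL)
    if (is.null(tr)) return(1e300)
    objective_sse(tr, series)
  }
  lo <- max(sc$cart$d, 1e-3)
  f_lo <- obj(lo)
  hi <- lo
  f_hi <- f_lo
  repeat {
    cand <- hi * 2
    if (cand > d_max) break
    f_cand <- obj(cand)
    if (f_cand > f_hi && f_hi <= f_lo) break  # past the minimum
    hi <- cand
    f_hi <- f_cand
  }
  if (hi <= lo) stop("no bracket found: objective does not improve above the initial guess")
  opt <- optimize(obj, lower = lo, upper = min(2 * hi, d_max))
  list(d = opt$minimum, objective = opt$objective, bracket = c(lo, hi))
}

#' Fit specification for latin-hypercube refinement
#'
#' @param names Free parameter names.
#' @param lower,upper Finite bounds per parameter (lower < upper).
#' @param batch LHS sample size per round.
#' @param n_rounds Maximum refinement rounds.
#' @param keep_best Number of top runs used to re-center the box.
#' @param shrink Box width multiplier per round.
#' @param seed RNG seed (required for reproducibility).
#' @return Object of class `"fit_spec"`.
#' @export
fit_spec <- function(names, lower, upper, batch = 20, n_rounds = 5,
                     keep_best = 3, shrink = 0.5, seed = 1) {
  stopifnot(length(names) == length(lower), length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper), keep_best >= 1, keep_best <= batch)
  structure(list(names = names, lower = setNames(lower, names),
                 upper = setNames(upper, names), batch = batch,
                 n_rounds = n_rounds, keep_best = keep_best,
                 shrink = shrink, seed = seed), class = "fit_spec")
}

#' Iterative latin-hypercube refinement
#'
#' Per round: draw an LHS sample over the current box, evaluate the
#' objective, re-center the box on the mean of the `keep_best` best
#' parameter vectors evaluated so far, and shrink its width; the search
#' stops after `n_rounds`, or earlier once the best objective has improved
#' by less than 1% on two consecutive rounds (random refinement commonly
#' stalls for a single round before the shrinking box catches up with the
#' incumbent).  If a round yields no finite objective the box is widened
#' once, then the search aborts.
#'
#' @param spec A [fit_spec()].
#' @param objective Function taking a named parameter vector, returning a
#'   scalar (may be `Inf` for failed simulations).
#' @return List with `par` (best vector), `objective`, and `history`
#'   (per-round best objective, box bounds and best parameters).
#' @export
lhs_refine <- function(spec, objective) {
  stopifnot(inherits(spec, "fit_spec"))
  set.seed(spec$seed)
  lo <- spec$lower
  hi <- spec$upper
  d <- length(spec$names)
  pool_par <- matrix(numeric(0), 0, d)
  pool_val <- numeric(0)
  widened <- FALSE
  stalls <- 0L
  history <- list()
  for (round in seq_len(spec$n_rounds)) {
    X <- lhs::randomLHS(spec$batch, d)
    pars <- sweep(sweep(X, 2, hi - lo, `*`), 2, lo, `+`)
    colnames(pars) <- spec$names
    vals <- apply(pars, 1, function(p) objective(setNames(p, spec$names)))
    if (all(!is.finite(vals))) {
      if (widened) {
        warning("all objective evaluations failed twice; aborting")
        break
      }
      width <- hi - lo
      lo <- pmax(spec$lower, lo - width / 2)
      hi <- pmin(spec$upper, hi + width / 2)
      widened <- TRUE
      next
    }
    prev_best <- if (length(pool_val)) min(pool_val) else Inf
    pool_par <- rbind(pool_par, pars)
    pool_val <- c(pool_val, vals)
    # re-center on the mean of the best runs seen so far and shrink
    keep <- order(pool_val)[seq_len(min(spec$keep_best,
                                        sum(is.finite(pool_val))))]
    center <- colMeans(pool_par[keep, , drop = FALSE])
    width <- (hi - lo) * spec$shrink
    lo <- pmax(spec$lower, center - width / 2)
    hi <- pmin(spec$upper, center + width / 2)
    round_best <- min(pool_val)
    history[[length(history) + 1L]] <-
      list(best = round_best, lower = lo, upper = hi,
           par = setNames(pool_par[which.min(pool_val), ], spec$names))
    improved <- (prev_best - round_best) / max(prev_best,
                                               .Machine$double.xmin)
    stalls <- if (round > 1 && (!is.finite(improved) || improved < 0.01))
      stalls + 1L else 0L
    if (stalls >= 2L) break
  }
  if (length(pool_val) == 0L || all(!is.finite(pool_val)))
    return(list(par = NULL, objective = Inf, history = history))
  best_idx <- which.min(pool_val)
  list(par = setNames(pool_par[best_idx, ], spec$names),
       objective = pool_val[best_idx], history = history)
}

#' Generate synthetic observation series
#'
#' Simulates a scenario, samples the requested population totals at the
#' given times, and applies multiplicative lognormal noise with unit mean
#' and coefficient of variation `noise_cv`.  Emulates the two mouse-study
#' designs: pre-treatment growth points followed by post-injection
#' decline, or joint short-horizon tumor + CAR T series.
#'
#' @param sc A [scenario()] (use `mode = "none"` for untreated growth).
#' @param sample_times Observation times (days from simulation start).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = exact model values).
#' @param seed RNG seed.
#' @param populations Character vector, subset of `c("tumor", "cart")`.
#' @param dr,dt Solver resolution.
#' @return Named list of [time_series()] objects.
#' @export
generate_synthetic_series <- function(sc, sample_times, noise_cv = 0,
                                      seed = 1,
                                      populations = "tumor",
                                      dr = 0.005, dt = 0.0025) {
  stopifnot(noise_cv >= 0)
  sc$horizon <- max(sc$horizon, max(sample_times))
  tr <- run_scenario(sc, dr = dr,
                     control = solver_config(dt = dt, record_every = 0.25,
                                             stop_tumor_below = 1))
  set.seed(seed)
  out <- list()
  for (pop in populations) {
    m <- .model_at(tr, sample_times, pop)
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      m <- m * exp(rnorm(length(m), -sdlog^2 / 2, sdlog))  # unit-mean noise
    }
    out[[pop]] <- time_series(sample_times, m, population = pop)
  }
  out
}
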