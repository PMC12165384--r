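test_that("nodes follow the logistic closed form when diffusion is off", {
  # u below the threshold everywhere: every node is an independent
  # logistic ODE with known solution
  tp <- tumor_params(a = 0.25, D_T = 1e-4, u_star = 2e8)
  grid <- radial_grid(0.5, dr = 0.01)
  u0 <- 1e7 * exp(-grid$r^2 / 0.05)
  st <- state_field(u0, rep(0, length(u0)), 0, 0, grid)
  tr <- simulate(st, tp, NULL, horizon = 10,
                 control = solver_config(dt = 0.003, record_every = 10))
  logistic <- function(u0, t) u0 * exp(tp$a * t) /
    (1 + tp$b * u0 * (exp(tp$a * t) - 1))
  interior <- seq_len(length(u0) - 1)  # r_max node is the Dirichlet anchor
  expect_lt(max(abs(tr$state$u[interior] - logistic(u0[interior], 10)) /
                logistic(u0[interior], 10)), 1e-3)
})

test_that("pure diffusion conserves CAR T mass under zero-flux boundaries", {
  tp <- tumor_params(a = 0.1, D_T = 1e-5, u_star = 1e8)
  cp <- cart_params(D_C = 0.05, d = 0, s = 1, l = 1, j = 0, k = 1, m = 0,
                    q = 0)
  grid <- radial_grid(1, dr = 0.01)
  v0 <- 1e8 * exp(-(grid$r - 0.3)^2 / 0.01)
  st <- state_field(rep(0, length(v0)), v0, 0, 0, grid)
  total0 <- state_totals(st)$effector
  nsteps <- 200
  tr <- simulate(st, tp, cp, horizon = nsteps * 0.01,
                 control = solver_config(dt = 0.01, record_every = 0.1))
  total1 <- state_totals(tr$state)$effector
  # relative drift per step below 1e-6
  expect_lt(abs(total1 - total0) / total0 / nsteps, 1e-6)
})

test_that("a uniform supra-threshold field stays uniform", {
  tp <- tumor_params(a = 1e-9, D_T = 1e-4, u_star = 1e7)
  grid <- radial_grid(0.5, dr = 0.01)
  u0 <- rep(2e8, length(grid$r))
  st <- state_field(u0, rep(0, length(u0)), 0, 0, grid)
  step <- cn_step(st, tp, NULL, dt = 0.01)
  # away from the far-field Dirichlet anchor the constant field is exact
  interior <- seq_len(length(u0) - 10)
  expect_lt(diff(range(step$u[interior])) / 2e8, 1e-9)
})

test_that("well-mixed limit matches an independent three-ODE integration", {
  skip_if_not_installed("deSolve")
  # u0 held below the diffusion threshold so the tumor operator is inert
  tp <- tumor_params(a = 0.2, D_T = 1e-5, u_star = 2.3e8)
  cp <- cart_params(D_C = 0, d = 0.9, s = 1.5, l = 2, j = 3, k = 4e15,
                    m = 0.35, q = 6e-9)
  grid <- radial_grid(0.3, dr = 0.01)
  n <- length(grid$r)
  u0 <- 2e8
  v0 <- 5e7
  # spatially uniform, zero diffusion: the PDE collapses to 3 ODEs
  st <- state_field(rep(u0, n), rep(v0, n), V_E = 1e6, t = 0, grid)
  tr <- simulate(st, tp, cp, horizon = 5,
                 control = solver_config(dt = 0.002, record_every = 1))
  # the outer node is pinned to 0 by the far-field condition and its cell
  # contributes no exhaustion influx
  vol <- sum(grid$w[-n])
  rhs <- function(t, y, parms) {
    u <- y[1]; v <- y[2]
    list(c(tumor_forcing(u, v, tp, cp),
           cart_forcing(u, v, cp),
           -cp$m * y[3] + cp$q * u * v * vol))
  }
  ode <- deSolve::ode(c(u0, v0, 1e6), seq(0, 5, by = 0.5), rhs, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-4)
  final <- ode[nrow(ode), ]
  # compare interior node densities (the Dirichlet anchor at r_max is 0)
  expect_equal(tr$state$u[1], unname(final[2]), tolerance = 1e-4)
  expect_equal(tr$state$v[1], unname(final[3]), tolerance = 1e-4)
  expect_equal(tr$state$V_E, unname(final[4]), tolerance = 1e-3)
})

test_that("state stays nonnegative and clamping is negligible in treatment runs", {
  st <- mouse_state(0.15)
  st2 <- init_intracavitary(st, 1e7)
  tr <- simulate(st2, fast_tumor(), cart_preset("skovgard"), horizon = 6,
                 control = solver_config(dt = 0.002, record_every = 0.5,
                                         stop_tumor_below = 1))
  expect_true(all(tr$state$u >= 0))
  expect_true(all(tr$state$v >= 0))
  total_cells <- max(tr$series$tumor[1], tr$series$effector[1])
  expect_lt(tr$clamped_mass / total_cells, 1e-6)
})

test_that("automatic step rule and growth-sized grids follow their recipes", {
  tp <- tumor_preset("typeI")
  cp <- cart_params(D_C = 1.38, d = 1, s = 1, l = 1, j = 1, k = 1,
                    m = 0.1, q = 0)
  expect_equal(dt_rule(tp, cp, dr = 0.015),
               min(0.25 * 0.015 / 1.38, 0.015 / 5))
  # Fisher-front travel bound: 1 cm tumor, 200-day horizon, type I
  g <- build_grid(1, 200, tp)
  expect_gte(g$r_max, 1 + 200 * 2 * sqrt(0.25 * 1e-5) + 1)
  g0 <- build_grid(0.5, 0, tp)
  expect_gte(g0$r_max, 0.5 + 1)
})

test_that("day-56 burden is stable under grid and step refinement", {
  # same treated scenario at (dr, dt) and (dr/2, dt/2)
  tp <- fast_tumor()
  cp <- cart_preset("default")
  burden56 <- function(dr, dt) {
    st <- grow_to_size(tp, 0.2, dr = dr)
    st2 <- init_intratumoral(st, 2e6, r_inj = 0.1)
    tr <- simulate(st2, tp, cp, horizon = 56,
                   control = solver_config(dt = dt, record_every = 2))
    tr$series$tumor[nrow(tr$series)]
  }
  b1 <- burden56(0.005, 0.01)
  b2 <- burden56(0.0025, 0.005)
  expect_lt(abs(b1 - b2) / b2, 0.02)
})

test_that("trajectories export CSV series, fields and a JSON manifest", {
  st <- mouse_state(0.15)
  tr <- simulate(st, fast_tumor(), NULL, horizon = 1,
                 control = solver_config(dt = 0.01, record_every = 0.5,
                                         snapshot_every = 0.5))
  out <- tempfile()
  files <- export_trajectory(tr, out, prefix = "tst", seed = 7)
  expect_true(all(file.exists(files)))
  series <- read.csv(files[["series"]])
  expect_true(all(c("t", "tumor", "effector", "r_detect") %in%
                  names(series)))
  fields <- read.csv(files[["fields"]])
  expect_true(all(c("time", "r", "u", "v") %in% names(fields)))
  man <- jsonlite::read_json(files[["manifest"]])
  expect_equal(man$seed, 7)
  expect_equal(man$grid$dr, 0.005)
  expect_equal(man$tumor$a, 0.25)
  unlink(out, recursive = TRUE)
})

test_that("early-stop events fire: eradication and radius target", {
  st <- mouse_state(0.15)
  st2 <- init_intracavitary(st, 1e7)
  tr <- simulate(st2, fast_tumor(), cart_preset("skovgard"), horizon = 8,
                 control = solver_config(dt = 0.002, record_every = 0.25,
                                         stop_tumor_below = 1))
  expect_equal(tr$stop_reason, "eradication")
  expect_lt(max(tr$series$t), 8)
  tr2 <- simulate(st, fast_tumor(), NULL, horizon = 100,
                  control = solver_config(dt = 0.01, record_every = 0.5,
                                          stop_radius_above = 0.18))
  expect_equal(tr2$stop_reason, "radius_target")
  expect_gte(tr2$series$r_detect[nrow(tr2$series)], 0.18)
})
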