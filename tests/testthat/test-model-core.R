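test_that("lysis rate matches the ratio-dependent kill law", {
  p <- cart_params(D_C = 0, d = 0.45, s = 1, l = 1, j = 0, k = 1, m = 0,
                   q = 0)
  # no killers, nothing to kill
  expect_identical(lysis_rate(1e8, 0, p), 0)
  expect_identical(lysis_rate(0, 1e6, p), 0)
  # half-saturation: (v/u)^l = s gives d*u/2
  expect_equal(lysis_rate(1e6, 1e6, p), 0.45 * 0.5 * 1e6)
  # direct substitution, cross-checked by an independent scalar evaluation
  u <- 1e6; v <- 1e6
  expect_equal(lysis_rate(u, v, p), 2.25e5)
  p2 <- cart_params(D_C = 0, d = 2, s = 1.5, l = 2, j = 0, k = 1, m = 0,
                    q = 0)
  ratio_term <- (v / u)^2 / (1.5 + (v / u)^2)
  expect_equal(lysis_rate(u, v, p2), 2 * ratio_term * u)
  expect_error(lysis_rate(-1, 1, p), "nonnegative")
})

test_that("lysis rate is monotone in v and bounded by d*u", {
  p <- cart_params(D_C = 0, d = 1.3, s = 0.7, l = 1.5, j = 0, k = 1,
                   m = 0, q = 0)
  u <- 10^seq(4, 8.3, length.out = 7)
  for (ui in u) {
    v <- 10^seq(2, 10, length.out = 40)
    rates <- lysis_rate(rep(ui, 40), v, p)
    expect_true(all(diff(rates) >= -1e-9 * max(rates)))
    expect_true(all(rates <= 1.3 * ui * (1 + 1e-12)))
    expect_true(all(rates >= 0))
  }
})

test_that("tumor forcing is logistic growth minus lysis", {
  tp <- tumor_params(a = 0.25, D_T = 1e-5, u_star = 1.2e8)
  cp <- cart_params(D_C = 0, d = 0.9, s = 1.5, l = 2, j = 0, k = 1, m = 0,
                    q = 0)
  expect_equal(tumor_forcing(1 / tp$b, 0, tp, cp), 0)  # carrying capacity
  expect_equal(tumor_forcing(0, 1e7, tp, cp), 0)       # empty stays empty
  # exponential-growth limit when u << 1/b
  expect_equal(tumor_forcing(1e6, 0, tp, cp), 0.25 * 1e6,
               tolerance = 0.01)
  # sign structure of untreated logistic growth
  expect_gt(tumor_forcing(1e8, 0, tp, cp), 0)
  expect_lt(tumor_forcing(1.1 / tp$b, 0, tp, cp), 0)
})

test_that("CAR T forcing has the right limits and saturation bound", {
  cp <- cart_params(D_C = 0, d = 2, s = 1, l = 1, j = 1.2, k = 1e10,
                    m = 0.3, q = 1e-9)
  # no tumor: pure death
  expect_equal(cart_forcing(0, 5e6, cp), -0.3 * 5e6)
  expect_equal(cart_forcing(1e8, 0, cp), 0)
  # saturated proliferation: D^2 >> k
  u <- 1e8; v <- 1e9
  D <- lysis_rate(u, v, cp)
  expect_gt(D^2 / cp$k, 1e4)
  expect_equal(cart_forcing(u, v, cp),
               (cp$j - cp$m - cp$q * u) * v, tolerance = 0.01)
  # proliferation saturates: F2 <= (j - m) v everywhere
  for (ui in 10^seq(3, 8, length.out = 6))
    for (vi in 10^seq(3, 9, length.out = 6))
      expect_lte(cart_forcing(ui, vi, cp), (cp$j - cp$m) * vi + 1e-9)
})

test_that("exhausted-cell balance integrates the influx over the tumor volume", {
  grid <- radial_grid(1, dr = 0.01)
  cp <- cart_params(D_C = 0, d = 0, s = 1, l = 1, j = 0, k = 1, m = 0.4,
                    q = 2e-9)
  # uniform u, v on a ball of radius R: Q = q*u*v*(4/3)*pi*R^3
  R <- 0.5
  u <- ifelse(grid$r <= R, 1e8, 0)
  v <- ifelse(grid$r <= R, 1e6, 0)
  st <- state_field(u, v, V_E = 1e5, t = 0, grid)
  got <- exhausted_rhs(st, cp, grid)
  # the discrete ball spans the cells of all nodes with r <= R, i.e. a
  # sphere of radius R + dr/2
  Q_exact <- 2e-9 * 1e8 * 1e6 * 4 * pi / 3 * (R + grid$dr / 2)^3
  expect_equal(got, -0.4 * 1e5 + Q_exact, tolerance = 0.001)
  # no tumor: pure exponential decay of the exhausted pool
  st0 <- state_field(rep(0, length(grid$r)), v, V_E = 1e5, t = 0, grid)
  expect_equal(exhausted_rhs(st0, cp, grid), -0.4 * 1e5)
})

test_that("V_E follows closed-form exponential decay when q = 0", {
  tp <- fast_tumor()
  cp <- cart_params(D_C = 0.01, d = 0, s = 1, l = 1, j = 0, k = 1,
                    m = 0.5, q = 0)
  grid <- radial_grid(0.5, dr = 0.01)
  st <- state_field(rep(0, length(grid$r)), rep(0, length(grid$r)),
                    V_E = 1e6, t = 0, grid)
  tr <- simulate(st, tp, cp, horizon = 4,
                 control = solver_config(dt = 0.01, record_every = 1))
  expect_equal(tr$state$V_E, 1e6 * exp(-0.5 * 4), tolerance = 1e-6)
})

test_that("parameter objects validate their invariants", {
  expect_error(tumor_params(a = -0.1, D_T = 1e-5, u_star = 1e7),
               "positive")
  expect_error(tumor_params(a = 0.1, D_T = 1e-5, u_star = 3e8),
               "carrying capacity")
  expect_error(cart_params(D_C = 0.01, d = 1, s = 1, l = 0.5, j = 1,
                           k = 1, m = 0.1, q = 0), "l must be >= 1")
  expect_error(detection_config(u_detect = 0), "u_detect")
  expect_s3_class(tumor_preset("typeIII"), "tumor_params")
  # Table-1 presets span the documented parameter ranges
  presets <- lapply(c("typeI", "typeII", "typeIII", "typeIV"), tumor_preset)
  a_vals <- vapply(presets, `[[`, 0, "a")
  expect_equal(range(a_vals), c(0.025, 0.25))
  expect_true(all(vapply(presets, function(p) p$u_star <= 1 / p$b, TRUE)))
})

test_that("parameter sets round-trip through YAML and JSON configs", {
  tp <- tumor_preset("typeII")
  cp <- cart_preset("default")
  det <- detection_config()
  for (ext in c("yaml", "json")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_params(f, tp = tp, cp = cp, det = det)
    back <- read_params(f)
    expect_equal(unclass(back$tumor), unclass(tp))
    expect_equal(unclass(back$cart), unclass(cp))
    expect_equal(back$det$u_detect, det$u_detect)
    unlink(f)
  }
})
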