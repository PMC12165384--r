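test_that("detectable radius interpolates the detection crossing", {
  grid <- radial_grid(1, dr = 0.01)
  # uniform ball at 2e8 (> 1e8 threshold) of radius 0.5
  u <- ifelse(grid$r <= 0.5, 2e8, 0)
  st <- state_field(u, rep(0, length(u)), 0, 0, grid)
  expect_equal(detectable_radius(st), 0.5, tolerance = 0.01 / 0.5)
  # everywhere below threshold: nothing detectable
  st2 <- state_field(rep(5e7, length(u)), rep(0, length(u)), 0, 0, grid)
  expect_equal(detectable_radius(st2), 0)
  # outermost crossing wins for non-monotone (treated) profiles
  u3 <- ifelse(grid$r <= 0.2, 5e7, ifelse(grid$r <= 0.4, 2e8, 0))
  st3 <- state_field(u3, rep(0, length(u3)), 0, 0, grid)
  expect_gt(detectable_radius(st3), 0.39)
})

test_that("burden summaries integrate the density field", {
  grid <- radial_grid(1, dr = 0.005)
  u <- ifelse(grid$r <= 0.4, 2e8, 0)
  st <- state_field(u, rep(0, length(u)), 0, 0, grid)
  b <- burdens(st)
  expect_equal(b$total, 2e8 * 4 * pi / 3 * 0.4025^3, tolerance = 1e-6)
  expect_lte(b$detectable, b$total)
  expect_equal(b$avg_density, 2e8, tolerance = 0.02)
  empty <- state_field(rep(0, length(u)), rep(0, length(u)), 0, 0, grid)
  be <- burdens(empty)
  expect_equal(be$total, 0)
  expect_true(is.na(be$avg_density))
})

test_that("grown invasive profiles extend beyond their detectable radius", {
  st <- grow_to_size(tumor_preset("typeIII"), 1.0)
  rd <- detectable_radius(st)
  r_extent <- max(st$grid$r[st$u > 1])
  expect_gt(r_extent, rd + 0.1)  # undetected low-density front
  # compact type I: detectable core is near carrying capacity
  st1 <- grow_to_size(tumor_preset("typeI"), 1.0)
  b <- burdens(st1)
  expect_equal(b$avg_density, 2.39e8, tolerance = 0.05)
})

test_that("VDT and TTP recover the scale of an exponential toy volume", {
  tau <- 12
  t <- seq(0, 40, by = 1)
  vol <- 1 * 2^(t / tau)
  r <- (3 * vol / (4 * pi))^(1 / 3)
  tr <- fake_traj(t, r_detect = r)
  got <- vdt_ttp(tr)
  expect_equal(got$vdt, tau, tolerance = 0.02)
  # TTP: diameter factor 1.2 = volume factor 1.728 -> tau*log2(1.728)
  expect_equal(got$ttp, tau * log2(1.2^3), tolerance = 0.02)
  # events beyond the trajectory are flagged, not fabricated
  short <- fake_traj(t[1:5], r_detect = r[1:5])
  expect_true(is.na(vdt_ttp(short)$vdt))
})

test_that("RECIST labels follow the diameter thresholds", {
  t <- seq(0, 56, by = 1)
  # complete disappearance
  cr <- fake_traj(t, r_detect = pmax(1 - t / 20, 0))
  expect_equal(classify_recist(2, cr, 56), "CR")
  # 35% diameter decrease
  pr <- fake_traj(t, r_detect = 1 - 0.35 * pmin(t / 30, 1))
  expect_equal(classify_recist(2, pr, 56), "PR")
  # 25% increase
  pd <- fake_traj(t, r_detect = 1 + 0.25 * pmin(t / 30, 1))
  expect_equal(classify_recist(2, pd, 56), "PD")
  # progression is irreversible: transient +25% then shrink back
  bump <- fake_traj(t, r_detect = 1 + 0.25 * sin(pi * pmin(t / 40, 1)))
  expect_equal(classify_recist(2, bump, 56), "PD")
  # within -30%..+20%: stable disease
  sd <- fake_traj(t, r_detect = rep(0.95, length(t)))
  expect_equal(classify_recist(2, sd, 56), "SD")
})

test_that("Choi labels accept either density or size response", {
  t <- seq(0, 56, by = 1)
  r <- rep(1, length(t))
  # density falls to 0.8x baseline, diameter unchanged -> PR under Choi
  dens_fold <- 1 - 0.2 * pmin(t / 30, 1)
  detc <- 1e8 * dens_fold * 4 * pi / 3 * r^3
  tr <- fake_traj(t, r_detect = r, detectable = detc)
  expect_equal(classify_choi(2, tr, 56), "PR")
  expect_equal(classify_recist(2, tr, 56), "SD")  # RECIST sees no change
  # 12% diameter decrease, density flat
  tr2 <- fake_traj(t, r_detect = 1 - 0.12 * pmin(t / 30, 1))
  expect_equal(classify_choi(2, tr2, 56), "PR")
  # no change in either
  tr3 <- fake_traj(t, r_detect = r)
  expect_equal(classify_choi(2, tr3, 56), "SD")
  # diameter +15% with no density response
  tr4 <- fake_traj(t, r_detect = 1 + 0.15 * pmin(t / 30, 1))
  expect_equal(classify_choi(2, tr4, 56), "PD")
})

test_that("outcome records summarize nadir, peak and eradication", {
  st <- mouse_state(0.15)
  st2 <- init_intracavitary(st, 1e7)
  tr <- simulate(st2, fast_tumor(), cart_preset("skovgard"), horizon = 8,
                 control = solver_config(dt = 0.002, record_every = 0.1,
                                         stop_tumor_below = 1))
  rec <- outcome_record(tr, eval_time = 8)
  expect_equal(rec$recist, "CR")
  expect_equal(rec$choi, "CR")
  expect_false(is.na(rec$t_eradication))
  expect_gt(rec$peak_cart, 1e7)  # expansion above the injected dose
  expect_lt(rec$nadir_cells, 10)
})

test_that("outcome maps classify each dose/exhaustion cell", {
  m <- outcome_map(fast_tumor(), "intracavitary",
                   doses = c(0, 1e7), exhausted_fractions = c(0, 1),
                   cart = cart_preset("skovgard"), treat_diameter = 0.3,
                   eval_time = 8, horizon = 8, dr = 0.005)
  expect_s3_class(m, "outcome_map")
  expect_equal(nrow(m), 4)
  # a fully exhausted or absent dose cannot beat this fast-growing tumor
  expect_true(all(m$recist[m$dose == 0] == "PD"))
  expect_true(all(m$recist[m$exhausted_fraction == 1] == "PD"))
  # full effector dose eradicates
  expect_equal(m$recist[m$dose == 1e7 & m$exhausted_fraction == 0], "CR")
  f <- tempfile(fileext = ".csv")
  write_outcome_map(m, f)
  expect_equal(nrow(read.csv(f)), 4)
  unlink(f)
})

test_that("minimum effective dose brackets the eradication threshold", {
  md <- min_effective_dose(fast_tumor(), "intracavitary",
                           cart = cart_preset("skovgard"),
                           treat_diameter = 0.3, horizon = 8,
                           dose_range = c(1e5, 1e7), tol_factor = 1.2,
                           dr = 0.005)
  expect_true(md$achieved)
  expect_true(md$dose >= 1e5 && md$dose <= 1e7)
  # success is monotone across the bracket: double the found dose works
  sc <- scenario(fast_tumor(), cart_preset("skovgard"),
                 mode = "intracavitary", dose = 2 * md$dose,
                 treat_diameter = 0.3, horizon = 8)
  tr <- run_scenario(sc, dr = 0.005,
                     control = solver_config(dt = 0.002,
                                             stop_tumor_below = 1))
  expect_equal(tr$stop_reason, "eradication")
  # a kill-less product never succeeds: flagged, not fabricated
  md0 <- min_effective_dose(fast_tumor(), "intracavitary",
                            cart = weak_cart(), treat_diameter = 0.3,
                            horizon = 2, dose_range = c(1e5, 1e6),
                            dr = 0.005)
  expect_false(md0$achieved)
  expect_true(is.na(md0$dose))
})

test_that("dose predictor regressions recover engineered relationships", {
  # perfectly collinear: log dose is linear in log predictor
  df <- data.frame(min_dose = 10^seq(7, 9, length.out = 6),
                   avg_density = 10^seq(7.5, 8.5, length.out = 6),
                   a_over_DT = 10^seq(2, 4, length.out = 6))
  set.seed(42)
  df$total_burden <- 10^runif(6, 8, 10)  # unrelated by construction
  df$vdt <- 10^runif(6, 1, 2)
  res <- dose_predictors(df)
  expect_equal(res$r_squared[res$predictor == "avg_density"], 1)
  expect_equal(res$r_squared[res$predictor == "a_over_DT"], 1)
  expect_lt(res$r_squared[res$predictor == "total_burden"], 0.7)
  # engineered predictors outrank the noise ones
  expect_true(all(res$predictor[1:2] %in% c("avg_density", "a_over_DT")))
  expect_error(dose_predictors(df[1:2, ]), "at least 3")
  df$flat <- 1
  expect_error(dose_predictors(df, predictors = "flat"), "degenerate")
})

test_that("sensitivity sweeps summarize nadir and peak per parameter value", {
  base <- scenario(fast_tumor(), cart_preset("skovgard"),
                   mode = "intracavitary", dose = 3e6,
                   treat_diameter = 0.3, horizon = 8)
  sw <- sensitivity_sweep("d", c(1, 6), base = base, dr = 0.005)
  expect_equal(nrow(sw), 2)
  expect_lte(sw$nadir[2], sw$nadir[1])  # stronger killing, deeper nadir
  expect_error(sensitivity_sweep("nope", 1, base = base), "unknown")
  # a single-value grid equals a direct run
  one <- sensitivity_sweep("d", 6, base = base, dr = 0.005)
  direct <- outcome_record(run_scenario(base, dr = 0.005), eval_time = 8)
  expect_equal(one$nadir, direct$nadir_cells, tolerance = 0.05)
})
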