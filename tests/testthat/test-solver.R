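test_that("a saturated strip is an equilibrium of the solver", {
  med <- cf4$medium
  med$permeability <- 1e-12
  med$initial_saturation <- 1 - 1e-9
  fld <- simulate_wicking(med, cf4$wetting, cf4$nonwetting, cf4$geometry,
                          cf4$closure,
                          solver_control(cell_count = 32,
                                         output_times = c(60, 240)))
  expect_lt(max(abs(fld$S - med$initial_saturation)), 1e-9)
})

test_that("saturation stays bounded and monotone along the strip", {
  fld <- cf4_field_obs()
  expect_gte(min(fld$S), cf4$medium$initial_saturation - 1e-9)
  expect_lte(max(fld$S), 1 + 1e-9)
  for (i in seq_along(fld$times)) {
    expect_true(all(diff(fld$S[i, ]) <= 1e-12))
  }
})

test_that("discrete mass budget closes against the inlet flux", {
  fld <- cf4_field_obs()
  expect_lt(fld$mass_balance_rel_err, 1e-8)
  am <- absorbed_mass(fld)
  expect_lt(max(abs(am$mass_kg - am$inflow_mass_kg) / am$inflow_mass_kg),
            1e-6)
  expect_true(all(diff(am$mass_kg) >= 0))
  # bounded by the strip pore volume worth of fluid
  cap <- cf4$wetting$density * cf4$medium$porosity *
    cross_section_area(cf4$geometry) * cf4$geometry$length
  expect_lte(max(am$mass_kg), cap)
})

test_that("fully imbibed strip holds rho * eps_p * V * (1 - S0) of fluid", {
  fld <- cf4_field_obs()
  am <- absorbed_mass(fld)
  cap <- 1000 * 0.8 * 0.0075 * 4.82e-4 * 0.06
  expect_equal(cap * (1 - 0.01), 1.7179e-4, tolerance = 1e-4)
  # at 240 s the strip is nearly full; never above the ceiling
  expect_lte(am$mass_kg[6], cap * (1 - 0.01) * (1 + 1e-9))
  expect_gt(am$mass_kg[6], 0.85 * cap * (1 - 0.01))
})

test_that("calibrated front follows sqrt(t) (log-log slope 0.5)", {
  tr <- front_position(cf4_field_early())
  fit <- lm(log(front_m) ~ log(time_s), data = tr)
  expect_equal(unname(coef(fit)[2]), 0.5, tolerance = 0.1)
  expect_true(all(diff(tr$front_m) >= 0))
})

test_that("solver and Lucas-Washburn agree in the capillary regime", {
  tr <- front_position(cf4_field_early())
  lwp <- lw_params_from_preset(cf4, permeability = cf4_K_lw())
  keep <- tr$time_s >= 10 & tr$time_s <= 60
  rel <- abs(tr$front_m[keep] - lw_front(lwp, tr$time_s[keep])) /
    lw_front(lwp, tr$time_s[keep])
  expect_lt(max(rel), 0.15)
})

test_that("halving the cell width moves the 60 s front by under 2%", {
  f60_coarse <- front_position(cf4_field(120, 60))$front_m
  f60_fine <- front_position(cf4_field(240, 60))$front_m
  expect_lt(abs(f60_fine - f60_coarse) / f60_fine, 0.02)
})

test_that("front readoff interpolates threshold crossings", {
  # synthetic fields: uniform dry profile reads zero everywhere
  mk_field <- function(S_row, n = length(S_row), L0 = 0.06) {
    dx <- L0 / n
    structure(list(x = (seq_len(n) - 0.5) * dx, times = 1,
                   S = matrix(S_row, nrow = 1),
                   medium = cf4$medium, geom = derive_geometry(L0),
                   control = solver_control(cell_count = max(n, 8),
                                            output_times = 1)),
              class = "wick_field")
  }
  expect_equal(front_position(mk_field(rep(0.01, 30)), 0.5)$front_m, 0)
  # step profile: S = 1 for x < 0.02 m, 0.01 beyond; threshold 0.5
  step <- c(rep(1, 10), rep(0.01, 20))
  expect_equal(front_position(mk_field(step), 0.5)$front_m, 0.02,
               tolerance = 0.002 / 0.02 * 0.5)
  # everything above threshold reads the full strip length
  expect_equal(front_position(mk_field(rep(0.9, 30)), 0.5)$front_m, 0.06)
  expect_error(front_position(mk_field(step), 0.005),
               class = "paperwick_validation_error")
})

test_that("air viscosity slows counter-current imbibition monotonically", {
  # displaced air leaves through the wet inlet, so a stiffer gas phase
  # throttles uptake; front must decrease monotonically with mu_air
  f <- function(mu) {
    front_position(cf4_field(64, 60,
                             nonwetting = air_fluid(viscosity = mu)))$front_m
  }
  fronts <- vapply(c(1.76e-6, 1.76e-5, 1.76e-4), f, numeric(1))
  expect_true(all(diff(fronts) < 0))
})

test_that("orientation parameter is inert while gravity is off", {
  flat <- cf4_field(48, 30)
  tilt <- simulate_wicking(flat$medium, cf4$wetting, cf4$nonwetting,
                           cf4$geometry, cf4$closure,
                           solver_control(cell_count = 48, output_times = 30,
                                          inclination = 0.7))
  expect_identical(flat$S, tilt$S)
  expect_error(simulate_wicking(flat$medium, cf4$wetting, cf4$nonwetting,
                                cf4$geometry, cf4$closure,
                                solver_control(cell_count = 48,
                                               output_times = 30,
                                               gravity_enabled = TRUE)),
               class = "paperwick_validation_error")
})

test_that("solver rejects uncalibrated media and bad controls", {
  expect_error(simulate_wicking(cf4$medium, cf4$wetting, cf4$nonwetting,
                                cf4$geometry, cf4$closure),
               class = "paperwick_validation_error")
  expect_error(solver_control(cell_count = 4),
               class = "paperwick_validation_error")
  expect_error(solver_control(front_threshold = 1),
               class = "paperwick_validation_error")
  expect_error(solver_control(output_times = c(10, 5)),
               class = "paperwick_validation_error")
})

test_that("single-equation solver matches the two-pressure formulation", {
  K <- cf4_K_solver()
  times <- c(20, 40, 60)
  fv <- front_position(cf4_field(32, times))$front_m
  imp <- impes_simulate(K, cf4$medium$porosity, cf4$wetting$viscosity,
                        cf4$nonwetting$viscosity,
                        cf4$medium$entry_capillary_pressure, 2,
                        0.01, 0.06, 32, times)
  f_or <- impes_front(imp, 0.5, 0.06)
  expect_lt(max(abs(fv - f_or) / f_or), 0.03)
})

test_that("saturation field tidies to a long table", {
  fld <- cf4_field(32, c(30, 60))
  td <- tidy(fld)
  expect_equal(nrow(td), 64)
  expect_named(td, c("time_s", "x_m", "saturation"))
  expect_equal(td$saturation[td$time_s == 60],
               unname(fld$S[2, ]))
  g <- glance(fld)
  expect_equal(g$cells, 32)
})
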