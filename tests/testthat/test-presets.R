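test_that("CF4 preset reproduces the reference parameter set", {
  p <- membrane_preset("CF4")
  expect_equal(p$membrane$wicking_rate, 67.3)
  expect_equal(p$membrane$thickness, 482e-6)
  expect_equal(p$medium$porosity, 0.80)
  expect_equal(p$medium$pore_radius, 2.25e-6)
  expect_equal(p$medium$entry_capillary_pressure, 47498, tolerance = 1 / 47498)
  expect_equal(p$medium$pore_size_distribution_index, 2)
  expect_equal(p$medium$initial_saturation, 0.01)
  expect_equal(p$geometry$length, 0.06)
  expect_equal(p$geometry$width, 0.0075)
  expect_equal(p$geometry$thickness, 4.82e-4)
  expect_equal(p$wetting$viscosity, 0.002)
  expect_equal(p$wetting$density, 1000)
  expect_equal(p$nonwetting$viscosity, 1.76e-5)
  expect_equal(p$wetting$surface_tension, 0.072)
})

test_that("MF1 and Fusion 5 presets apply the half-pore-diameter rule", {
  mf1 <- membrane_preset("MF1")
  expect_equal(mf1$medium$pore_radius, 0.225e-6)
  expect_equal(mf1$membrane$wicking_rate, 29.7)
  expect_equal(mf1$medium$porosity, 0.69)
  expect_equal(mf1$membrane$thickness, 367e-6)

  f5 <- membrane_preset("Fusion5")
  expect_equal(f5$medium$pore_radius, mean(c(21e-6, 181e-6)) / 2)
  expect_equal(f5$membrane$wicking_rate, 43.9)
  expect_equal(f5$membrane$pore_diameter, c(21e-6, 181e-6))
})

test_that("preset lookup is case-insensitive and rejects unknown names", {
  expect_equal(membrane_preset("fusion5"), membrane_preset("Fusion5"))
  expect_equal(membrane_preset("Fusion 5"), membrane_preset("Fusion5"))
  expect_equal(membrane_preset("cf4"), membrane_preset("CF4"))
  err <- expect_error(membrane_preset("nitrocellulose"),
                      class = "paperwick_unknown_membrane")
  expect_match(conditionMessage(err), "CF4")
  expect_match(conditionMessage(err), "Fusion5")
})

test_that("rc_policy switches CF4 between reference and half-pore radius", {
  paper <- membrane_preset("CF4", rc_policy = "paper")
  half <- membrane_preset("CF4", rc_policy = "half_pore")
  expect_equal(paper$medium$pore_radius, 2.25e-6)
  expect_equal(half$medium$pore_radius, 5.5e-6)
  # entry pressure follows the radius
  expect_equal(half$medium$entry_capillary_pressure,
               paper$medium$entry_capillary_pressure * 2.25 / 5.5)
})

test_that("geometry derivation applies the W0 = L0/8 rule and validates", {
  expect_equal(derive_geometry(0.06)$width, 0.0075)
  expect_equal(derive_geometry(0.08)$width, 0.01)
  expect_error(derive_geometry(0), class = "paperwick_validation_error")
  expect_error(derive_geometry(-1), class = "paperwick_validation_error")
})

test_that("parameter constructors enforce their physical invariants", {
  expect_error(fluid_spec(density = -1, viscosity = 1e-3),
               class = "paperwick_validation_error")
  expect_error(fluid_spec(1000, 0.002, contact_angle = pi / 2),
               class = "paperwick_validation_error")
  expect_error(porous_medium(porosity = 1, pore_radius = 1e-6,
                             entry_capillary_pressure = 1e4),
               class = "paperwick_validation_error")
  expect_error(porous_medium(0.8, 1e-6, 1e4,
                             residual_saturations = c(0.6, 0.5)),
               class = "paperwick_validation_error")
  expect_error(membrane_spec("x", "y", 1e-4, 60, c(2e-6, 1e-6), 0.5),
               class = "paperwick_validation_error")
})

test_that("presets survive a config-file round trip unchanged", {
  for (name in membrane_names()) {
    p <- membrane_preset(name)
    path <- withr::local_tempfile(fileext = ".yaml")
    write_wick_config(p, path)
    p2 <- preset_from_config(read_wick_config(path))
    expect_equal(p2, p, tolerance = 1e-12)
  }
})

test_that("every simulation-table parameter maps into the config", {
  table_names <- c("D1", "D2", "epsilon1", "L0", "W0", "th", "sigma", "Rc",
                   "pec", "lp", "por", "rho_air", "rho_saliva", "mu_air",
                   "mu_saliva")
  cfg <- as_wick_config(membrane_preset("CF4"))
  expect_true(all(table_names %in% names(cfg)))
  # and the stored values are the reference ones
  expect_equal(cfg$D1, 2.15e-6)
  expect_equal(cfg$D2, 1e-5)
  expect_equal(cfg$epsilon1, 0.383)
  expect_equal(cfg$L0, 0.06)
  expect_equal(cfg$W0, 0.0075)
  expect_equal(cfg$th, 4.82e-4)
  expect_equal(cfg$rho_saliva, 1000)
  expect_equal(cfg$mu_air, 1.76e-5)
})

test_that("unknown configuration keys are a hard error", {
  p <- membrane_preset("CF4")
  expect_error(paperwick:::apply_config_values(p, list(viscocity = 1)),
               class = "paperwick_unknown_key")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(membrane = "CF4", porosity_pct = 80), path)
  expect_error(read_wick_config(path), class = "paperwick_unknown_key")
})

test_that("overriding sigma/theta/Rc recomputes the entry pressure", {
  p <- membrane_preset("CF4")
  p2 <- paperwick:::apply_config_values(p, list(Rc = 4.5e-6))
  expect_equal(p2$medium$entry_capillary_pressure,
               p$medium$entry_capillary_pressure / 2)
  expect_equal(p2$closure$entry_pressure,
               p2$medium$entry_capillary_pressure)
  # explicit pec wins over recomputation
  p3 <- paperwick:::apply_config_values(p, list(Rc = 4.5e-6, pec = 1234))
  expect_equal(p3$medium$entry_capillary_pressure, 1234)
})
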