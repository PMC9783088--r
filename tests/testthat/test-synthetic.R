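true_trace <- tibble::tibble(time_s = c(20, 40, 60, 120, 180, 240),
                             front_m = c(0.021, 0.031, 0.038, 0.053,
                                         0.058, 0.060))

test_that("noise-free readings reduce to ruler quantization", {
  nm <- noise_model(front_sd = 0, quantization = 0.005, seed = 1)
  tr <- tibble::tibble(time_s = 10, front_m = 0.042)
  expect_equal(synth_front_readings(tr, nm)$front_m, 0.040)
  # millimetre grid leaves these values alone
  nm2 <- noise_model(front_sd = 0, quantization = 0.001, seed = 1)
  out <- synth_front_readings(true_trace, nm2)
  expect_equal(out$front_m, true_trace$front_m)
  expect_equal(attr(out, "source"), "synthetic")
})

test_that("generators are reproducible under a fixed seed", {
  nm <- noise_model(seed = 99)
  expect_equal(synth_front_readings(true_trace, nm),
               synth_front_readings(true_trace, nm))
  expect_equal(synth_analyte_profile("CF4", "DNA", noise = nm),
               synth_analyte_profile("CF4", "DNA", noise = nm))
  expect_equal(synth_viscosity_series("stimulated", nm),
               synth_viscosity_series("stimulated", nm))
  # different seeds decorrelate
  nm2 <- noise_model(seed = 100)
  expect_false(isTRUE(all.equal(synth_front_readings(true_trace, nm),
                                synth_front_readings(true_trace, nm2))))
})

test_that("front noise matches its nominal standard deviation", {
  nm <- noise_model(front_sd = 0.002, quantization = 0, seed = 7)
  one <- tibble::tibble(time_s = rep(30, 1e4), front_m = rep(0.03, 1e4))
  reads <- synth_front_readings(one, nm)
  expect_equal(sd(reads$front_m - 0.03), 0.002, tolerance = 0.03)
  expect_equal(mean(reads$front_m - 0.03), 0, tolerance = 1e-4)
})

test_that("readings stay on the strip", {
  nm <- noise_model(front_sd = 0.02, quantization = 0.001, seed = 3)
  edge <- tibble::tibble(time_s = 1:200,
                         front_m = rep(c(0.001, 0.059), 100))
  out <- synth_front_readings(edge, nm, strip_length = 0.06)
  expect_gte(min(out$front_m), 0)
  expect_lte(max(out$front_m), 0.06)
})

test_that("noise-free analyte profiles carry the anchored levels", {
  quiet <- noise_model(concentration_cv = 0)
  cf4_dna <- synth_analyte_profile("CF4", "DNA", noise = quiet)
  expect_equal(nrow(cf4_dna), 6)
  expect_equal(cf4_dna$concentration_ng_ul[1:2], c(400, 400))
  expect_equal(cf4_dna$concentration_ng_ul[5], 700) # 4-5 cm segment
  expect_equal(cf4_dna$x_max_m, seq(0.01, 0.06, by = 0.01))

  f5_dna <- synth_analyte_profile("Fusion5", "DNA", noise = quiet)
  expect_equal(f5_dna$concentration_ng_ul[1:2], c(400, 400))

  mf1_dna <- synth_analyte_profile("MF1", "DNA", noise = quiet)
  expect_equal(mf1_dna$concentration_ng_ul[1:4], rep(200, 4))
  expect_lt(max(mf1_dna$concentration_ng_ul), 400)

  # cv = 0 output is identical whatever the seed
  expect_equal(synth_analyte_profile("CF4", "DNA",
                                     noise = noise_model(concentration_cv = 0,
                                                         seed = 1)),
               synth_analyte_profile("CF4", "DNA",
                                     noise = noise_model(concentration_cv = 0,
                                                         seed = 2)))
  expect_error(synth_analyte_profile("CF4", "lipid", noise = quiet))
  expect_error(synth_analyte_profile("blot", "DNA", noise = quiet),
               class = "paperwick_unknown_membrane")
})

test_that("analyte concentrations are never negative", {
  nm <- noise_model(concentration_cv = 1, seed = 5)
  for (a in c("DNA", "RNA", "protein")) {
    prof <- synth_analyte_profile("MF1", a, "unstimulated", nm)
    expect_true(all(prof$concentration_ng_ul >= 0))
  }
})

test_that("viscosity series has 21 points around the reported means", {
  quiet <- noise_model(concentration_cv = 0)
  ss <- synth_viscosity_series("stimulated", quiet)
  us <- synth_viscosity_series("unstimulated", quiet)
  expect_equal(nrow(ss), 21)
  expect_equal(ss$viscosity_pa_s, rep(0.002, 21))
  expect_equal(us$viscosity_pa_s, rep(0.00234, 21))
  expect_error(synth_viscosity_series("lukewarm", quiet))
})

test_that("unstimulated saliva reads more viscous across seeds", {
  hits <- sum(vapply(1:100, function(s) {
    nm <- noise_model(concentration_cv = 0.01, seed = s)
    mean(synth_viscosity_series("unstimulated", nm)$viscosity_pa_s) >
      mean(synth_viscosity_series("stimulated", nm)$viscosity_pa_s)
  }, logical(1)))
  expect_gte(hits, 95)
})

test_that("sqrt-t coefficient is recovered from noisy quantized traces", {
  truth <- front_position(cf4_field_obs())
  c_true <- fit_front_law(truth[truth$time_s <= 60, ])$value
  errs <- vapply(1:200, function(s) {
    nm <- noise_model(front_sd = 0.001, quantization = 0.001, seed = s)
    noisy <- synth_front_readings(truth, nm)
    # fit over the pre-saturation window where the law applies
    abs(fit_front_law(noisy[noisy$time_s <= 60, ])$value - c_true) / c_true
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
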