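# Shared fixtures: the CF4 preset and memoised calibrated solver runs, so
# expensive simulations are computed once per test session.

cf4 <- membrane_preset("CF4")

cf4_K_lw <- function() {
  permeability_from_wicking_rate(cf4$membrane, cf4$wetting, cf4$medium,
                                 model = "lw")$value
}

.memo <- new.env(parent = emptyenv())

memoise1 <- function(key, fn) {
  if (is.null(.memo[[key]])) .memo[[key]] <- fn()
  .memo[[key]]
}

cf4_K_solver <- function() {
  memoise1("K_solver", function() {
    permeability_from_wicking_rate(cf4$membrane, cf4$wetting, cf4$medium,
                                   model = "solver", geom = cf4$geometry,
                                   closure = cf4$closure)$value
  })
}

cf4_field <- function(cells, times, K = cf4_K_solver(),
                      nonwetting = cf4$nonwetting) {
  med <- cf4$medium
  med$permeability <- K
  simulate_wicking(med, cf4$wetting, nonwetting, cf4$geometry, cf4$closure,
                   solver_control(cell_count = cells, output_times = times))
}

# calibrated 240-cell run at the six observation times
cf4_field_obs <- function() {
  memoise1("field_obs", function() {
    cf4_field(240, c(20, 40, 60, 120, 180, 240))
  })
}

# calibrated 120-cell run densely sampled over the first minute
cf4_field_early <- function() {
  memoise1("field_early", function() cf4_field(120, seq(5, 60, by = 5)))
}
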