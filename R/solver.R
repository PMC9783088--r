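# 1-D two-phase Darcy saturation-transport solver.
#
# With incompressible phases, S_w + S_n = 1 and a closed far end, the total
# velocity vanishes and the phase-transport system reduces to one nonlinear
# capillary-diffusion equation for the wetting saturation,
#   eps_p dS/dt = d/dx( K * (lam_w lam_n/(lam_w+lam_n)) * (-dpc/dS) * dS/dx ),
# solved by an explicit conservative finite-volume scheme (src/).

#' Solver configuration
#'
#' @param cell_count Number of finite-volume cells (>= 8; default 240 over
#'   the 6 cm strip, i.e. 0.25 mm cells).
#' @param output_times Times (s) at which the saturation field is recorded;
#'   default the six observation times 20-240 s.
#' @param front_threshold Saturation defining the visible dye front,
#'   strictly in (0, 1); default 0.5.
#' @param cfl_safety Fraction of the explicit stability limit used for the
#'   adaptive step (in (0, 1]).
#' @param min_time_step Hard failure below this step size (s).
#' @param max_steps Step budget before the run aborts.
#' @param gravity_enabled Gravity term switch. Strips lie horizontal, so the
#'   default is `FALSE`; `TRUE` is rejected by [simulate_wicking()].
#' @param inclination Strip inclination (radians) from horizontal; inert
#'   while gravity is disabled.
#' @param seed Reserved for stochastic extensions; the solver is
#'   deterministic and ignores it.
#' @return A `solver_control` list.
#' @export
solver_control <- function(cell_count = 240,
                           output_times = c(20, 40, 60, 120, 180, 240),
                           front_threshold = 0.5,
                           cfl_safety = 0.9,
                           min_time_step = 1e-9,
                           max_steps = 5e7,
                           gravity_enabled = FALSE,
                           inclination = 0,
                           seed = NULL) {
  check_number(cell_count, "cell_count", lower = 8)
  if (length(output_times) < 1L || any(output_times <= 0) ||
      is.unsorted(output_times, strictly = TRUE)) {
    abort("`output_times` must be strictly increasing and positive.",
          class = "paperwick_validation_error")
  }
  check_number(front_threshold, "front_threshold", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(cfl_safety, "cfl_safety", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_positive(min_time_step, "min_time_step")
  structure(list(cell_count = as.integer(cell_count),
                 output_times = as.numeric(output_times),
                 front_threshold = front_threshold,
                 cfl_safety = cfl_safety,
                 min_time_step = min_time_step,
                 max_steps = max_steps,
                 gravity_enabled = isTRUE(gravity_enabled),
                 inclination = inclination,
                 seed = seed),
            class = "solver_control")
}

#' Simulate two-phase imbibition along a paper strip
#'
#' Evolves the wetting (saliva) saturation on a uniform 1-D grid from a dry
#' initial state (`medium$initial_saturation`, default 0.01) with the inlet
#' cell face held at full saturation (strip end dipped in a reservoir) and a
#' no-flow far end. The scheme is conservative: the discrete stored-mass
#' change equals the integrated inlet flux at every step.
#'
#' @param medium A [porous_medium()] with calibrated `permeability`.
#' @param wetting,nonwetting [fluid_spec()]s for saliva and air.
#' @param geom A [strip_geometry()].
#' @param closure A [brooks_corey()] closure; defaults to one built from the
#'   medium's entry pressure and pore-size-distribution index.
#' @param control A [solver_control()].
#' @return A `wick_field` object: cell centers `x` (m), `times` (s), the
#'   saturation matrix `S` (times by cells), the cumulative inlet Darcy flux
#'   `cum_inflow` (m), the inputs, and solver diagnostics (`n_steps`,
#'   `dt_min`, `mass_balance_rel_err`).
#' @examples
#' \donttest{
#' preset <- membrane_preset("CF4")
#' cal <- permeability_from_wicking_rate(preset$membrane, preset$wetting,
#'                                       preset$medium)
#' preset$medium$permeability <- cal$value
#' fld <- simulate_wicking(preset$medium, preset$wetting, preset$nonwetting,
#'                         preset$geometry,
#'                         control = solver_control(cell_count = 120))
#' front_position(fld)
#' }
#' @export
simulate_wicking <- function(medium, wetting, nonwetting, geom,
                             closure = NULL, control = solver_control()) {
  stopifnot(inherits(medium, "porous_medium"),
            inherits(wetting, "fluid_spec"),
            inherits(nonwetting, "fluid_spec"),
            inherits(geom, "strip_geometry"),
            inherits(control, "solver_control"))
  if (is.na(medium$permeability)) {
    abort("`medium$permeability` is uncalibrated; run permeability_from_wicking_rate() first.",
          class = "paperwick_validation_error")
  }
  if (control$gravity_enabled) {
    abort("Gravity transport is not implemented: strips are modelled horizontal.",
          class = "paperwick_validation_error")
  }
  closure <- closure %||% brooks_corey(medium$entry_capillary_pressure,
                                       medium$pore_size_distribution_index)
  n <- control$cell_count
  dx <- geom$length / n
  res <- fv_imbibition(n_cells = n, dx = dx,
                       K = medium$permeability,
                       eps_p = medium$porosity,
                       mu_w = wetting$viscosity,
                       mu_n = nonwetting$viscosity,
                       pec = closure$entry_pressure,
                       lp = closure$index,
                       s_init = medium$initial_saturation,
                       s_inlet = 1,
                       sr_w = medium$residual_saturations[["wetting"]],
                       sr_n = medium$residual_saturations[["nonwetting"]],
                       out_times = control$output_times,
                       cfl_safety = control$cfl_safety,
                       min_dt = control$min_time_step,
                       se_floor = 1e-9,
                       max_steps = control$max_steps)
  structure(list(x = (seq_len(n) - 0.5) * dx,
                 times = control$output_times,
                 S = res$S,
                 cum_inflow = res$cum_inflow,
                 medium = medium, wetting = wetting,
                 nonwetting = nonwetting, geom = geom,
                 closure = closure, control = control,
                 n_steps = res$n_steps, dt_min = res$dt_min,
                 mass_balance_rel_err = res$mass_balance_rel_err),
            class = "wick_field")
}

#' @export
print.wick_field <- function(x, ...) {
  cat(sprintf("<wick_field> %d cells x %d times (t = %g..%g s)\n",
              length(x$x), length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  %.0f steps, dt_min %.3g s, mass-balance resid %.2g\n",
              x$n_steps, x$dt_min, x$mass_balance_rel_err))
  invisible(x)
}

#' Tidy a saturation field into long format
#'
#' @param x A `wick_field`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `x_m`, `saturation`.
#' @export
tidy.wick_field <- function(x, ...) {
  tibble(time_s = rep(x$times, each = length(x$x)),
         x_m = rep(x$x, times = length(x$times)),
         saturation = as.vector(t(x$S)))
}

#' @export
glance.wick_field <- function(x, ...) {
  tibble(cells = length(x$x), n_times = length(x$times),
         n_steps = x$n_steps, dt_min = x$dt_min,
         mass_balance_rel_err = x$mass_balance_rel_err,
         min_saturation = min(x$S), max_saturation = max(x$S))
}

# interpolated rightmost position where S >= threshold on one profile of
# cell-center values; 0 when even the first cell is below threshold
front_from_profile <- function(x, S, threshold, L0) {
  above <- S >= threshold
  if (!above[1]) return(0)
  j <- max(which(above))
  if (j == length(S)) return(L0)
  x[j] + (S[j] - threshold) / (S[j] - S[j + 1]) * (x[j + 1] - x[j])
}

#' Wicking front trajectory of a saturation field
#'
#' For each output time, the largest position whose linearly interpolated
#' saturation still reaches `threshold` (the visible dye front); 0 when no
#' cell does, the strip length when even the last cell is above threshold.
#'
#' @param field A `wick_field` from [simulate_wicking()].
#' @param threshold Front saturation threshold, strictly between the initial
#'   saturation and 1; defaults to the solver control's value.
#' @return A tibble `time_s`, `front_m` with attribute
#'   `source = "simulated"`.
#' @export
front_position <- function(field, threshold = NULL) {
  stopifnot(inherits(field, "wick_field"))
  threshold <- threshold %||% field$control$front_threshold
  check_number(threshold, "threshold",
               lower = field$medium$initial_saturation, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  front <- vapply(seq_along(field$times), function(i) {
    front_from_profile(field$x, field$S[i, ], threshold, field$geom$length)
  }, numeric(1))
  out <- tibble(time_s = field$times, front_m = front)
  attr(out, "source") <- "simulated"
  out
}

#' Absorbed mass of a saturation field
#'
#' `m(t) = rho * eps_p * width * thickness * sum((S - S0) * dx)`:
#' the imbibed pore volume above the initial saturation times the fluid
#' density. By mass conservation this equals the time-integral of the inlet
#' mass flux.
#'
#' @param field A `wick_field`.
#' @param geom,medium,fluid Override the field's stored strip geometry,
#'   medium and wetting fluid (defaults: those used in the run).
#' @return A tibble `time_s`, `mass_kg`, `inflow_mass_kg` (the flux-integral
#'   cross-check) with attribute `source = "simulated"`.
#' @export
absorbed_mass <- function(field, geom = field$geom, medium = field$medium,
                          fluid = field$wetting) {
  stopifnot(inherits(field, "wick_field"))
  dx <- geom$length / length(field$x)
  area <- cross_section_area(geom)
  stored <- rowSums(field$S - medium$initial_saturation) * dx *
    medium$porosity
  out <- tibble(time_s = field$times,
                mass_kg = fluid$density * area * stored,
                inflow_mass_kg = fluid$density * area * field$cum_inflow)
  attr(out, "source") <- "simulated"
  out
}
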