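# Calibration of quantities no data sheet or parameter table provides:
# permeability (from the manufacturer wicking rate), contact angle (from the
# entry capillary pressure), and sqrt-t front-law coefficients from traces.

new_calibration <- function(parameter, value, anchor, residual, model = NA_character_) {
  structure(list(parameter = parameter, value = value, anchor = anchor,
                 residual = residual, model = model),
            class = "wick_calibration")
}

#' @export
print.wick_calibration <- function(x, ...) {
  cat(sprintf("<wick_calibration> %s = %.6g (%s)\n", x$parameter, x$value,
              if (is.na(x$model)) "direct" else x$model))
  cat(sprintf("  anchor: %s; residual: %.3g\n", x$anchor, x$residual))
  invisible(x)
}

#' @export
tidy.wick_calibration <- function(x, ...) {
  tibble(parameter = x$parameter, value = x$value, model = x$model,
         anchor = x$anchor, residual = x$residual)
}

#' @export
glance.wick_calibration <- function(x, ...) {
  tibble(value = x$value, residual = x$residual)
}

#' Calibrate permeability from the manufacturer wicking rate
#'
#' Membrane data sheets quote a wicking rate (seconds per 4 cm of travel)
#' but never a permeability. This inverts the chosen wicking model so that
#' its front reaches `anchor_length` at exactly the wicking time. For the
#' Lucas-Washburn model the inversion is closed-form; for the finite-volume
#' solver it exploits the exact invariance of the saturation equation under
#' `t -> K t`: a pilot run gives the anchor crossing time at a trial
#' permeability, the ratio rescales K, and a fixed-point refinement
#' continues until the re-simulated crossing time is within `tol_s`.
#'
#' Calibrating to the manufacturer rate (not to observed front traces)
#' keeps the downstream simulation-versus-observation comparison a genuine
#' prediction check.
#'
#' @param membrane A [membrane_spec()] (supplies the wicking rate).
#' @param fluid Wetting [fluid_spec()].
#' @param medium A [porous_medium()].
#' @param model `"lw"` (closed form) or `"solver"`.
#' @param geom,closure,control Solver inputs (solver model only); defaults:
#'   6 cm strip with the membrane thickness, closure from the medium, 240
#'   cells.
#' @param anchor_length Travel distance of the wicking-rate anchor (m),
#'   default 0.04.
#' @param tol_s Solver-mode tolerance on the reproduced anchor time (s).
#' @return A `wick_calibration` with `parameter = "permeability"`,
#'   `value` in m^2 and `residual` = |reproduced - target| anchor time (s).
#' @export
permeability_from_wicking_rate <- function(membrane, fluid, medium,
                                           model = c("lw", "solver"),
                                           geom = NULL, closure = NULL,
                                           control = NULL,
                                           anchor_length = 0.04,
                                           tol_s = 0.1) {
  stopifnot(inherits(membrane, "membrane_spec"),
            inherits(fluid, "fluid_spec"),
            inherits(medium, "porous_medium"))
  model <- match.arg(model)
  t_anchor <- membrane$wicking_rate
  check_positive(t_anchor, "wicking_rate")
  check_positive(anchor_length, "anchor_length")
  anchor_txt <- sprintf("front = %g m at %g s (manufacturer wicking rate)",
                        anchor_length, t_anchor)

  # closed-form LW inversion; also the pilot guess for the solver
  ct <- cos(fluid$contact_angle)
  K_lw <- anchor_length^2 * medium$porosity * fluid$viscosity *
    medium$pore_radius / (2 * fluid$surface_tension * ct * t_anchor)

  if (model == "lw") {
    return(new_calibration("permeability", K_lw, anchor_txt,
                           residual = 0, model = "lw"))
  }

  geom <- geom %||% derive_geometry(0.06, thickness = membrane$thickness)
  closure <- closure %||% brooks_corey(medium$entry_capillary_pressure,
                                       medium$pore_size_distribution_index)
  if (anchor_length >= geom$length) {
    abort("`anchor_length` must lie inside the strip.",
          class = "paperwick_validation_error")
  }

  crossing_time <- function(K) {
    med <- medium
    med$permeability <- K
    # dense front sampling around the expected crossing
    ctr <- solver_control(
      cell_count = if (is.null(control)) 240 else control$cell_count,
      output_times = seq(t_anchor / 40, 6 * t_anchor, length.out = 160),
      front_threshold = if (is.null(control)) 0.5 else control$front_threshold)
    fld <- simulate_wicking(med, fluid, air_fluid(), geom, closure, ctr)
    tr <- front_position(fld)
    if (max(tr$front_m) < anchor_length) {
      # no crossing within the window: sqrt(t)-extrapolate its time
      return(max(tr$time_s) * (anchor_length / max(tr$front_m))^2)
    }
    i <- which(tr$front_m >= anchor_length)[1]
    if (i == 1) return(tr$time_s[1])
    approx(tr$front_m[(i - 1):i], tr$time_s[(i - 1):i],
           xout = anchor_length, ties = "ordered")$y
  }

  K <- K_lw
  resid <- Inf
  for (it in 1:8) {
    T0 <- crossing_time(K)
    resid <- abs(T0 - t_anchor)
    if (resid <= tol_s) break
    # front position depends on K and t only through K * t, so the
    # crossing time rescales exactly as 1/K
    K <- K * T0 / t_anchor
  }
  if (!is.finite(resid) || resid > tol_s) {
    abort(sprintf("solver permeability calibration did not converge (residual %.3g s)",
                  resid),
          class = "paperwick_calibration_error")
  }
  new_calibration("permeability", K, anchor_txt, residual = resid,
                  model = "solver")
}

#' Contact angle from the entry capillary pressure
#'
#' Exact inverse of the Young-Laplace expression
#' `pec = 2 sigma cos(theta) / Rc`: `theta = acos(pec Rc / (2 sigma))`.
#' With the reference values pec = 47,498 Pa, sigma = 0.072 N/m and
#' Rc = 2.25 um this yields about 42.07 degrees, the default wetting angle
#' of all presets.
#'
#' @param pec Entry capillary pressure (Pa), `>= 0`.
#' @param sigma Surface tension (N/m).
#' @param Rc Capillary radius (m).
#' @return Contact angle (radians).
#' @export
contact_angle_from_entry_pressure <- function(pec, sigma, Rc) {
  check_number(pec, "pec", lower = 0)
  check_positive(sigma, "sigma")
  check_positive(Rc, "Rc")
  x <- pec * Rc / (2 * sigma)
  if (x > 1) {
    abort(sprintf("inconsistent pec/sigma/Rc: cos(theta) would be %.4g > 1", x),
          class = "paperwick_validation_error")
  }
  acos(x)
}

#' Fit the one-parameter square-root front law to a trace
#'
#' Least-squares coefficient of `l = c * sqrt(t)`, which has the closed
#' form `c = sum(l_i sqrt(t_i)) / sum(t_i)`; the residual is the RMSE of
#' the fitted law at the trace times.
#'
#' @param trace A wicking trace tibble with columns `time_s` (> 0, at least
#'   two points) and `front_m`.
#' @return A `wick_calibration` with `parameter = "sqrt_t_coefficient"`
#'   (units m / sqrt(s)).
#' @export
fit_front_law <- function(trace) {
  if (!is.data.frame(trace) || nrow(trace) == 0L) {
    abort("`trace` must be a non-empty data frame.",
          class = "paperwick_validation_error")
  }
  if (!all(c("time_s", "front_m") %in% names(trace))) {
    abort("`trace` needs columns `time_s` and `front_m`.",
          class = "paperwick_validation_error")
  }
  if (nrow(trace) < 2L || any(trace$time_s <= 0)) {
    abort("Need at least two points with strictly positive times.",
          class = "paperwick_validation_error")
  }
  cc <- sum(trace$front_m * sqrt(trace$time_s)) / sum(trace$time_s)
  rmse <- sqrt(mean((trace$front_m - cc * sqrt(trace$time_s))^2))
  new_calibration("sqrt_t_coefficient", cc,
                  sprintf("least squares on %d points", nrow(trace)),
                  residual = rmse, model = "sqrt_t")
}
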