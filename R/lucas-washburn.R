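# Lucas-Washburn closed-form wicking law.

#' Lucas-Washburn parameter set
#'
#' @param permeability Intrinsic permeability K (m^2).
#' @param surface_tension Surface tension gamma (N/m).
#' @param contact_angle Contact angle theta (radians), in `[0, pi/2)`.
#' @param porosity Porosity phi, in (0, 1).
#' @param viscosity Dynamic viscosity mu (Pa s).
#' @param pore_radius Capillary radius r_a (m).
#' @param alpha Time exponent (default 1, the classical square-root law).
#' @return An `lw_params` list.
#' @export
lw_params <- function(permeability, surface_tension, contact_angle,
                      porosity, viscosity, pore_radius, alpha = 1) {
  check_positive(permeability, "permeability")
  check_positive(surface_tension, "surface_tension")
  check_number(contact_angle, "contact_angle", lower = 0, upper = pi / 2,
               strict_upper = TRUE)
  check_number(porosity, "porosity", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_positive(viscosity, "viscosity")
  check_positive(pore_radius, "pore_radius")
  check_positive(alpha, "alpha")
  structure(list(permeability = permeability,
                 surface_tension = surface_tension,
                 contact_angle = contact_angle, porosity = porosity,
                 viscosity = viscosity, pore_radius = pore_radius,
                 alpha = alpha),
            class = "lw_params")
}

#' Assemble Lucas-Washburn parameters from a membrane preset
#'
#' @param preset A [membrane_preset()].
#' @param permeability Permeability (m^2); defaults to the preset's medium
#'   permeability (which must have been calibrated).
#' @param alpha Time exponent.
#' @return An [lw_params()] object.
#' @export
lw_params_from_preset <- function(preset, permeability = NULL, alpha = 1) {
  stopifnot(inherits(preset, "wick_preset"))
  permeability <- permeability %||% preset$medium$permeability
  if (is.na(permeability)) {
    abort("Preset permeability is uncalibrated; supply `permeability` or run permeability_from_wicking_rate().",
          class = "paperwick_validation_error")
  }
  lw_params(permeability, preset$wetting$surface_tension,
            preset$wetting$contact_angle, preset$medium$porosity,
            preset$wetting$viscosity, preset$medium$pore_radius,
            alpha = alpha)
}

#' Lucas-Washburn front position
#'
#' The permeability form of the wicking law,
#' `l(t) = sqrt(2 K gamma cos(theta) t^alpha / (phi mu r_a))`; with
#' `alpha = 1` the wetted length grows exactly as the square root of time.
#' `variant = "classic"` gives the textbook single-capillary form
#' `l(t) = sqrt(gamma r_a cos(theta) t / (2 mu))`, useful as a sensitivity
#' check when no permeability is available.
#'
#' @param params An [lw_params()] set.
#' @param t Elapsed time (s), vectorized, `>= 0`.
#' @param variant `"permeability"` (default) or `"classic"`.
#' @return Front position (m).
#' @export
lw_front <- function(params, t, variant = c("permeability", "classic")) {
  stopifnot(inherits(params, "lw_params"))
  variant <- match.arg(variant)
  if (any(t < 0)) {
    abort("`t` must be non-negative.", class = "paperwick_validation_error")
  }
  ct <- cos(params$contact_angle)
  switch(variant,
    permeability = sqrt(2 * params$permeability * params$surface_tension *
                          ct * t^params$alpha /
                          (params$porosity * params$viscosity *
                             params$pore_radius)),
    classic = sqrt(params$surface_tension * params$pore_radius * ct * t /
                     (2 * params$viscosity))
  )
}

#' Time for the Lucas-Washburn front to reach a length
#'
#' Exact inverse of [lw_front()]: `lw_front(p, lw_time_to(p, L)) == L` to
#' floating precision.
#'
#' @inheritParams lw_front
#' @param L Target length (m), `>= 0`.
#' @return Time (s).
#' @export
lw_time_to <- function(params, L, variant = c("permeability", "classic")) {
  stopifnot(inherits(params, "lw_params"))
  variant <- match.arg(variant)
  if (any(L < 0)) {
    abort("`L` must be non-negative.", class = "paperwick_validation_error")
  }
  ct <- cos(params$contact_angle)
  switch(variant,
    permeability = (L^2 * params$porosity * params$viscosity *
                      params$pore_radius /
                      (2 * params$permeability * params$surface_tension *
                         ct))^(1 / params$alpha),
    classic = 2 * params$viscosity * L^2 /
      (params$surface_tension * params$pore_radius * ct)
  )
}

#' Absorbed fluid mass under the Lucas-Washburn law
#'
#' `m(t) = rho * phi * width * thickness * min(l(t), L0)`: the wetted pore
#' volume times the fluid density, saturating once the front reaches the
#' strip end.
#'
#' @inheritParams lw_front
#' @param geom A [strip_geometry()].
#' @param fluid A [fluid_spec()] for the imbibing fluid.
#' @return Absorbed mass (kg).
#' @export
lw_mass <- function(params, geom, fluid, t,
                    variant = c("permeability", "classic")) {
  stopifnot(inherits(geom, "strip_geometry"), inherits(fluid, "fluid_spec"))
  l <- pmin(lw_front(params, t, variant), geom$length)
  fluid$density * params$porosity * cross_section_area(geom) * l
}

#' Tabulate a Lucas-Washburn wicking trace
#'
#' @inheritParams lw_mass
#' @param times Output times (s), strictly increasing.
#' @return A tibble with columns `time_s`, `front_m` and, when `geom` and
#'   `fluid` are supplied, `mass_kg`; attribute `source = "simulated"`.
#' @export
lw_trace <- function(params, times, geom = NULL, fluid = NULL,
                     variant = c("permeability", "classic")) {
  variant <- match.arg(variant)
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.",
          class = "paperwick_validation_error")
  }
  out <- tibble(time_s = as.numeric(times),
                front_m = lw_front(params, times, variant))
  if (!is.null(geom)) {
    out$front_m <- pmin(out$front_m, geom$length)
    if (!is.null(fluid)) {
      out$mass_kg <- lw_mass(params, geom, fluid, times, variant)
    }
  }
  attr(out, "source") <- "simulated"
  out
}
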