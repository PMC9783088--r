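# Physical parameter containers and built-in membrane presets.
#
# All quantities are SI (m, s, kg, Pa, N/m, radians). Vendor data sheets and
# the simulation parameter set use mixed units (um, mm, cm, mN/m); conversion
# happens here, at the preset boundary, and nowhere else.

# Manufacturer characteristics of the three Whatman membranes.
# thickness (m, at 53 kPa), wicking_rate (s per 4 cm), pore_diameter (m,
# a range for Fusion 5), porosity (fraction).
.membrane_table <- list(
  CF4 = list(material = "100% cotton linter", thickness = 482e-6,
             wicking_rate = 67.3, pore_diameter = 11e-6, porosity = 0.80),
  MF1 = list(material = "bound glass fiber", thickness = 367e-6,
             wicking_rate = 29.7, pore_diameter = 0.45e-6, porosity = 0.69),
  Fusion5 = list(material = "glass fibre/polymer single-layer matrix",
                 thickness = 370e-6, wicking_rate = 43.9,
                 pore_diameter = c(21e-6, 181e-6), porosity = 0.80)
)

# Reference simulation constants (CF4-anchored): surface tension, CF4
# capillary radius and the printed CF4 entry capillary pressure from which
# the default contact angle is back-computed.
.default_surface_tension <- 0.072    # N/m
.cf4_pore_radius <- 2.25e-6          # m
.cf4_entry_pressure <- 47498         # Pa
.default_initial_saturation <- 0.01

#' Default wetting contact angle
#'
#' The contact angle is never measured directly; it is back-computed so that
#' the Young-Laplace entry-pressure expression `2*sigma*cos(theta)/Rc`
#' reproduces the reference CF4 entry capillary pressure of 47,498 Pa with
#' sigma = 0.072 N/m and Rc = 2.25 um (about 42.07 degrees).
#'
#' @return Contact angle in radians.
#' @export
default_contact_angle <- function() {
  contact_angle_from_entry_pressure(.cf4_entry_pressure,
                                    .default_surface_tension,
                                    .cf4_pore_radius)
}

#' Young-Laplace entry capillary pressure
#'
#' `pec = 2 * sigma * cos(theta) / Rc`: the capillary pressure at which the
#' non-wetting phase starts to be displaced from a pore of radius `Rc`.
#'
#' @param sigma Surface tension (N/m).
#' @param theta Contact angle (radians), in `[0, pi/2)`.
#' @param Rc Capillary (pore) radius (m).
#' @return Entry capillary pressure (Pa).
#' @export
entry_capillary_pressure <- function(sigma, theta, Rc) {
  check_positive(sigma, "sigma")
  check_number(theta, "theta", lower = 0, upper = pi / 2, strict_upper = TRUE)
  check_positive(Rc, "Rc")
  2 * sigma * cos(theta) / Rc
}

#' Membrane data-sheet description
#'
#' @param name Membrane identifier.
#' @param material Free-text material description.
#' @param thickness Sheet thickness (m).
#' @param wicking_rate Manufacturer wicking rate: seconds per 4 cm of travel.
#' @param pore_diameter Pore diameter (m); length-2 vector for a range.
#' @param porosity Void fraction, strictly in (0, 1).
#' @return A `membrane_spec` list.
#' @export
membrane_spec <- function(name, material, thickness, wicking_rate,
                          pore_diameter, porosity) {
  check_positive(thickness, "thickness")
  check_positive(wicking_rate, "wicking_rate")
  check_number(porosity, "porosity", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  if (!is.numeric(pore_diameter) || !length(pore_diameter) %in% 1:2 ||
      any(pore_diameter <= 0) || is.unsorted(pore_diameter)) {
    abort("`pore_diameter` must be one positive diameter or an increasing range.",
          class = "paperwick_validation_error")
  }
  structure(list(name = name, material = material, thickness = thickness,
                 wicking_rate = wicking_rate, pore_diameter = pore_diameter,
                 porosity = porosity),
            class = "membrane_spec")
}

#' Fluid phase properties
#'
#' @param density Density (kg/m^3).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param surface_tension Surface tension against air (N/m).
#' @param contact_angle Wetting contact angle on the membrane (radians),
#'   in `[0, pi/2)`.
#' @return A `fluid_spec` list.
#' @export
fluid_spec <- function(density, viscosity,
                       surface_tension = .default_surface_tension,
                       contact_angle = default_contact_angle()) {
  check_positive(density, "density")
  check_positive(viscosity, "viscosity")
  check_positive(surface_tension, "surface_tension")
  check_number(contact_angle, "contact_angle", lower = 0, upper = pi / 2,
               strict_upper = TRUE)
  structure(list(density = density, viscosity = viscosity,
                 surface_tension = surface_tension,
                 contact_angle = contact_angle),
            class = "fluid_spec")
}

#' Saliva and air phase presets
#'
#' Reference simulation values: saliva 1000 kg/m^3 and 0.002 Pa s
#' (stimulated saliva); air 1 kg/m^3 and 1.76e-5 Pa s.
#'
#' @inheritParams fluid_spec
#' @return A [fluid_spec()].
#' @export
saliva_fluid <- function(density = 1000, viscosity = 0.002,
                         surface_tension = .default_surface_tension,
                         contact_angle = default_contact_angle()) {
  fluid_spec(density, viscosity, surface_tension, contact_angle)
}

#' @rdname saliva_fluid
#' @export
air_fluid <- function(density = 1, viscosity = 1.76e-5) {
  fluid_spec(density, viscosity,
             surface_tension = .default_surface_tension, contact_angle = 0)
}

#' Strip geometry
#'
#' A rectangular paper strip of length `length`, width `width` and thickness
#' `thickness`; the cross-section area is `width * thickness`.
#'
#' @param length Strip length L0 (m).
#' @param width Strip width W0 (m).
#' @param thickness Strip thickness (m).
#' @return A `strip_geometry` list.
#' @export
strip_geometry <- function(length, width, thickness) {
  check_positive(length, "length")
  check_positive(width, "width")
  check_positive(thickness, "thickness")
  structure(list(length = length, width = width, thickness = thickness),
            class = "strip_geometry")
}

#' Derive strip geometry from its length
#'
#' The strip width follows the fixed aspect rule `W0 = L0 / 8` (0.0075 m for
#' the standard 6 cm strip).
#'
#' @param L0 Strip length (m).
#' @param thickness Strip thickness (m), from the membrane data sheet.
#' @return A [strip_geometry()].
#' @export
derive_geometry <- function(L0, thickness = 4.82e-4) {
  check_positive(L0, "L0")
  strip_geometry(length = L0, width = L0 / 8, thickness = thickness)
}

#' Cross-section area of a strip
#' @param geom A [strip_geometry()].
#' @return Area (m^2).
#' @export
cross_section_area <- function(geom) geom$width * geom$thickness

#' Porous medium parameters
#'
#' @param porosity Pore volume fraction epsilon_p, in (0, 1).
#' @param pore_radius Effective capillary radius Rc (m).
#' @param entry_capillary_pressure Entry capillary pressure pec (Pa).
#' @param pore_size_distribution_index Brooks-Corey index lp (> 0).
#' @param permeability Intrinsic permeability k (m^2). `NA` until calibrated:
#'   no membrane data sheet states it (see
#'   [permeability_from_wicking_rate()]).
#' @param initial_saturation Uniform initial wetting saturation of the dry
#'   strip (default 0.01).
#' @param residual_saturations Named pair `c(wetting =, nonwetting =)` of
#'   immobile saturation fractions; default both 0 (the initial saturation is
#'   an initial condition, not a residual).
#' @return A `porous_medium` list.
#' @export
porous_medium <- function(porosity, pore_radius, entry_capillary_pressure,
                          pore_size_distribution_index = 2,
                          permeability = NA_real_,
                          initial_saturation = .default_initial_saturation,
                          residual_saturations = c(wetting = 0, nonwetting = 0)) {
  check_number(porosity, "porosity", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_positive(pore_radius, "pore_radius")
  check_number(entry_capillary_pressure, "entry_capillary_pressure", lower = 0)
  check_positive(pore_size_distribution_index, "pore_size_distribution_index")
  check_number(permeability, "permeability", lower = 0, strict_lower = TRUE,
               allow_na = TRUE)
  check_number(initial_saturation, "initial_saturation", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (length(residual_saturations) != 2L || any(residual_saturations < 0) ||
      sum(residual_saturations) >= 1) {
    abort("`residual_saturations` must be two non-negative fractions summing below 1.",
          class = "paperwick_validation_error")
  }
  residual_saturations <- setNames(as.numeric(residual_saturations),
                                   c("wetting", "nonwetting"))
  structure(list(porosity = porosity, pore_radius = pore_radius,
                 entry_capillary_pressure = entry_capillary_pressure,
                 pore_size_distribution_index = pore_size_distribution_index,
                 permeability = permeability,
                 initial_saturation = initial_saturation,
                 residual_saturations = residual_saturations),
            class = "porous_medium")
}

#' Auxiliary simulation parameters
#'
#' Parameters carried by the reference simulation setup but unused by the
#' default solver: two diffusion coefficients whose role the setup never
#' states, a secondary porosity (0.383) listed alongside the transport
#' porosity of 0.8, and the gravitational acceleration (off by default;
#' strips lie horizontal).
#'
#' @param D1,D2 Diffusion coefficients (m^2/s).
#' @param gravity Gravitational acceleration (m/s^2); 0 disables.
#' @param epsilon1 Secondary porosity (stored, unused).
#' @return An `aux_params` list.
#' @export
aux_params <- function(D1 = 2.15e-6, D2 = 1e-5, gravity = 0,
                       epsilon1 = 0.383) {
  check_number(D1, "D1", lower = 0)
  check_number(D2, "D2", lower = 0)
  check_number(gravity, "gravity", lower = 0)
  check_number(epsilon1, "epsilon1", lower = 0)
  structure(list(D1 = D1, D2 = D2, gravity = gravity, epsilon1 = epsilon1),
            class = "aux_params")
}

#' Known membrane preset names
#' @return Character vector of valid membrane identifiers.
#' @export
membrane_names <- function() names(.membrane_table)

normalize_membrane <- function(name) {
  if (!is.character(name) || length(name) != 1L) {
    abort("Membrane name must be a single string.",
          class = "paperwick_validation_error")
  }
  key <- gsub("[^a-z0-9]", "", tolower(name))
  hit <- match(key, gsub("[^a-z0-9]", "", tolower(membrane_names())))
  if (is.na(hit)) {
    abort(sprintf("unknown membrane \"%s\"; valid names: %s", name,
                  paste(membrane_names(), collapse = ", ")),
          class = "paperwick_unknown_membrane")
  }
  membrane_names()[hit]
}

#' Built-in membrane presets
#'
#' Returns the full physical description of one of the three supported
#' lateral-flow membranes: the data-sheet [membrane_spec()], a
#' [porous_medium()], the standard 6 cm [strip_geometry()], the saliva/air
#' [fluid_spec()] pair and the Brooks-Corey [brooks_corey()] closure.
#'
#' The CF4 preset reproduces the reference simulation parameter set verbatim
#' (Rc = 2.25 um, porosity 0.8, thickness 482 um, L0 = 6 cm, W0 = L0/8).
#' Note that 2.25 um is *not* half the data-sheet pore diameter of 11 um;
#' `rc_policy = "half_pore"` switches to the half-pore-diameter rule used
#' for the other membranes (MF1: 0.225 um; Fusion 5: half the midpoint of
#' its 21-181 um range). Entry pressures for MF1/Fusion 5 are derived from
#' the same Young-Laplace expression with the default contact angle.
#'
#' @param name Membrane identifier, case-insensitive: `"CF4"`, `"MF1"` or
#'   `"Fusion5"`.
#' @param rc_policy How to pick the capillary radius for CF4:
#'   `"paper"` keeps the reference value 2.25 um (default), `"half_pore"`
#'   applies the half-pore-diameter rule.
#' @param surface_tension Saliva surface tension (N/m).
#' @param contact_angle Wetting contact angle (radians).
#' @param L0 Strip length (m).
#' @return A `wick_preset` list with elements `name`, `membrane`, `medium`,
#'   `geometry`, `wetting`, `nonwetting`, `closure`, `aux`, `rc_policy`.
#' @examples
#' p <- membrane_preset("CF4")
#' p$membrane$wicking_rate   # 67.3 s per 4 cm
#' p$geometry$width          # 0.0075 m
#' @export
membrane_preset <- function(name, rc_policy = c("paper", "half_pore"),
                            surface_tension = .default_surface_tension,
                            contact_angle = default_contact_angle(),
                            L0 = 0.06) {
  rc_policy <- match.arg(rc_policy)
  canonical <- normalize_membrane(name)
  row <- .membrane_table[[canonical]]
  spec <- membrane_spec(canonical, row$material, row$thickness,
                        row$wicking_rate, row$pore_diameter, row$porosity)
  half_pore <- mean(row$pore_diameter) / 2
  pore_radius <- if (canonical == "CF4" && rc_policy == "paper") {
    .cf4_pore_radius
  } else {
    half_pore
  }
  pec <- entry_capillary_pressure(surface_tension, contact_angle, pore_radius)
  medium <- porous_medium(porosity = row$porosity, pore_radius = pore_radius,
                          entry_capillary_pressure = pec)
  structure(list(name = canonical,
                 membrane = spec,
                 medium = medium,
                 geometry = derive_geometry(L0, thickness = row$thickness),
                 wetting = saliva_fluid(surface_tension = surface_tension,
                                        contact_angle = contact_angle),
                 nonwetting = air_fluid(),
                 closure = brooks_corey(pec, 2),
                 aux = aux_params(),
                 rc_policy = rc_policy),
            class = "wick_preset")
}

#' @export
print.wick_preset <- function(x, ...) {
  cat(sprintf("<wick_preset> %s (%s)\n", x$name, x$membrane$material))
  cat(sprintf("  strip: %.3g x %.3g x %.3g m, porosity %.2f\n",
              x$geometry$length, x$geometry$width, x$geometry$thickness,
              x$medium$porosity))
  cat(sprintf("  Rc = %.3g m (%s), pec = %.5g Pa, lp = %g\n",
              x$medium$pore_radius, x$rc_policy,
              x$medium$entry_capillary_pressure,
              x$medium$pore_size_distribution_index))
  cat(sprintf("  permeability: %s\n",
              if (is.na(x$medium$permeability)) "uncalibrated"
              else sprintf("%.4g m^2", x$medium$permeability)))
  invisible(x)
}
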