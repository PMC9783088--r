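# Brooks-Corey capillary closure and Darcy flux primitives.

#' Brooks-Corey closure model
#'
#' The closure is parameterized by exactly the two quantities the simulation
#' setup provides: the entry capillary pressure `pec` and the pore size
#' distribution index `lp`.
#'
#' @param entry_pressure Entry capillary pressure pec (Pa).
#' @param index Pore size distribution index lp (> 0).
#' @return A `closure_model` list.
#' @export
brooks_corey <- function(entry_pressure, index = 2) {
  check_number(entry_pressure, "entry_pressure", lower = 0)
  check_positive(index, "index")
  structure(list(entry_pressure = entry_pressure, index = index),
            class = "closure_model")
}

#' Effective (normalized) saturation
#'
#' Rescales a wetting saturation between the residual saturations to
#' `[0, 1]`: `Se = (S - Sr_w) / (1 - Sr_w - Sr_n)`, clamped.
#'
#' @param S Wetting saturation (vectorized).
#' @param residuals Pair of residual saturations `c(wetting, nonwetting)`,
#'   summing below 1.
#' @return Effective saturation in `[0, 1]`.
#' @export
effective_saturation <- function(S, residuals = c(0, 0)) {
  if (length(residuals) != 2L || any(residuals < 0) || sum(residuals) >= 1) {
    abort("`residuals` must be two non-negative fractions summing below 1.",
          class = "paperwick_validation_error")
  }
  pmin(pmax((S - residuals[[1]]) / (1 - sum(residuals)), 0), 1)
}

#' Brooks-Corey capillary pressure
#'
#' `pc(Se) = pec * Se^(-1/lp)`: equals the entry pressure at full
#' saturation and increases without bound as the medium dries. Non-positive
#' `Se` is regularized by capping at `pc_max` instead of diverging.
#'
#' @param Se Effective saturation, in `(0, 1]` (vectorized).
#' @param closure A [brooks_corey()] closure.
#' @param pc_max Cap applied where `Se <= 0` (default: the value at
#'   `Se = 1e-6`).
#' @return Capillary pressure (Pa).
#' @export
capillary_pressure <- function(Se, closure, pc_max = NULL) {
  stopifnot(inherits(closure, "closure_model"))
  if (any(Se > 1 + 1e-12, na.rm = TRUE)) {
    abort("`Se` must not exceed 1.", class = "paperwick_validation_error")
  }
  pec <- closure$entry_pressure
  lp <- closure$index
  pc_max <- pc_max %||% (pec * 1e-6^(-1 / lp))
  pc <- ifelse(Se <= 0, pc_max, pmin(pec * pmin(Se, 1)^(-1 / lp), pc_max))
  unname(pc)
}

#' Brooks-Corey relative permeabilities
#'
#' Wetting and non-wetting relative permeability pair:
#' `kr_w = Se^((2 + 3 lp) / lp)` and
#' `kr_n = (1 - Se)^2 * (1 - Se^((2 + lp) / lp))`, both in `[0, 1]` with the
#' single-phase limits `kr(1) = (1, 0)` and `kr(0) = (0, 1)`.
#'
#' @param Se Effective saturation in `[0, 1]` (vectorized).
#' @param lp Pore size distribution index.
#' @return A tibble with columns `Se`, `kr_wetting`, `kr_nonwetting`.
#' @export
rel_perm <- function(Se, lp = 2) {
  check_positive(lp, "lp")
  if (any(Se < -1e-12 | Se > 1 + 1e-12, na.rm = TRUE)) {
    abort("`Se` must lie in [0, 1].", class = "paperwick_validation_error")
  }
  Se <- pmin(pmax(Se, 0), 1)
  tibble(Se = Se,
         kr_wetting = Se^((2 + 3 * lp) / lp),
         kr_nonwetting = (1 - Se)^2 * (1 - Se^((2 + lp) / lp)))
}

#' Darcy flux
#'
#' `q = -(k * kr / mu) * dp/dx`; positive flux points toward increasing x.
#'
#' @param k Intrinsic permeability (m^2).
#' @param kr Relative permeability (dimensionless, in `[0, 1]`).
#' @param mu Dynamic viscosity (Pa s).
#' @param pressure_gradient Pressure gradient dp/dx (Pa/m), vectorized.
#' @return Darcy (superficial) velocity (m/s).
#' @export
darcy_flux <- function(k, kr, mu, pressure_gradient) {
  check_positive(k, "k")
  check_positive(mu, "mu")
  -(k * kr / mu) * pressure_gradient
}
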