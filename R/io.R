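# Delimited-text trace IO and structured configuration files.
#
# Files are comma-separated with a header row and '.' decimal; units are SI
# and carried in the column names (time_s, front_m, mass_kg).

#' Read a wicking trace from a delimited file
#'
#' Expects a header row with columns `time_s` and `front_m` (optionally
#' `mass_kg`). Missing columns, non-numeric cells and non-monotone times
#' each raise a distinct, named error.
#'
#' @param path Path to a comma-separated file.
#' @return A trace tibble.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("trace file not found: %s", path),
          class = "paperwick_parse_missing_file")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time_s", "front_m")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "paperwick_parse_missing_column")
  }
  keep <- intersect(c("time_s", "front_m", "mass_kg"), names(raw))
  for (col in keep) {
    if (!is.numeric(raw[[col]]) || anyNA(raw[[col]])) {
      abort(sprintf("non-numeric cell in column `%s`", col),
            class = "paperwick_parse_non_numeric")
    }
  }
  if (is.unsorted(raw$time_s, strictly = TRUE)) {
    abort("non-monotone time: `time_s` must be strictly increasing",
          class = "paperwick_parse_non_monotone_time")
  }
  as_tibble(raw[keep])
}

#' Write a wicking trace to a delimited file
#'
#' @param trace A trace tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# -- structured configuration -------------------------------------------------

#' Configuration keys understood by presets and overrides
#'
#' The numeric keys mirror the simulation parameter table (`sigma`, `Rc`,
#' `lp`, `por`, `pec`, `rho_saliva`, `mu_saliva`, `rho_air`, `mu_air`,
#' `L0`, `W0`, `th`, `D1`, `D2`, `epsilon1`) plus `theta`, `s_init` and
#' `permeability`.
#'
#' @return Character vector of valid keys.
#' @export
wick_config_keys <- function() {
  c("sigma", "theta", "Rc", "lp", "por", "pec",
    "rho_saliva", "mu_saliva", "rho_air", "mu_air",
    "L0", "W0", "th", "D1", "D2", "epsilon1",
    "s_init", "permeability")
}

#' Flatten a preset into a configuration list
#'
#' @param preset A [membrane_preset()].
#' @return Named list with `membrane`, `rc_policy` and every
#'   [wick_config_keys()] entry (SI units).
#' @export
as_wick_config <- function(preset) {
  stopifnot(inherits(preset, "wick_preset"))
  list(membrane = preset$name,
       rc_policy = preset$rc_policy,
       sigma = preset$wetting$surface_tension,
       theta = preset$wetting$contact_angle,
       Rc = preset$medium$pore_radius,
       lp = preset$medium$pore_size_distribution_index,
       por = preset$medium$porosity,
       pec = preset$medium$entry_capillary_pressure,
       rho_saliva = preset$wetting$density,
       mu_saliva = preset$wetting$viscosity,
       rho_air = preset$nonwetting$density,
       mu_air = preset$nonwetting$viscosity,
       L0 = preset$geometry$length,
       W0 = preset$geometry$width,
       th = preset$geometry$thickness,
       D1 = preset$aux$D1,
       D2 = preset$aux$D2,
       epsilon1 = preset$aux$epsilon1,
       s_init = preset$medium$initial_saturation,
       permeability = preset$medium$permeability)
}

#' Write / read a configuration file (YAML)
#'
#' @param config A configuration list (e.g. from [as_wick_config()]) or a
#'   `wick_preset`.
#' @param path File path.
#' @return `read_wick_config()` returns the configuration list;
#'   `write_wick_config()` returns `path` invisibly.
#' @export
write_wick_config <- function(config, path) {
  if (inherits(config, "wick_preset")) config <- as_wick_config(config)
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' @rdname write_wick_config
#' @export
read_wick_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path),
          class = "paperwick_parse_missing_file")
  }
  cfg <- yaml::read_yaml(path)
  known <- c("membrane", "rc_policy", wick_config_keys())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "paperwick_unknown_key")
  }
  cfg
}

# apply named numeric values onto a preset; pec is recomputed from
# sigma/theta/Rc when any of those change and pec itself is not given
apply_config_values <- function(preset, values) {
  unknown <- setdiff(names(values), wick_config_keys())
  if (length(unknown) > 0) {
    abort(sprintf("unknown parameter key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "paperwick_unknown_key")
  }
  has <- function(k) k %in% names(values)
  val <- function(k) as.numeric(values[[k]])
  if (has("sigma")) preset$wetting$surface_tension <- val("sigma")
  if (has("theta")) preset$wetting$contact_angle <- val("theta")
  if (has("Rc")) preset$medium$pore_radius <- val("Rc")
  if (has("lp")) {
    preset$medium$pore_size_distribution_index <- val("lp")
    preset$closure$index <- val("lp")
  }
  if (has("por")) preset$medium$porosity <- val("por")
  if (has("rho_saliva")) preset$wetting$density <- val("rho_saliva")
  if (has("mu_saliva")) preset$wetting$viscosity <- val("mu_saliva")
  if (has("rho_air")) preset$nonwetting$density <- val("rho_air")
  if (has("mu_air")) preset$nonwetting$viscosity <- val("mu_air")
  if (has("L0")) {
    preset$geometry$length <- val("L0")
    if (!has("W0")) preset$geometry$width <- val("L0") / 8
  }
  if (has("W0")) preset$geometry$width <- val("W0")
  if (has("th")) preset$geometry$thickness <- val("th")
  if (has("D1")) preset$aux$D1 <- val("D1")
  if (has("D2")) preset$aux$D2 <- val("D2")
  if (has("epsilon1")) preset$aux$epsilon1 <- val("epsilon1")
  if (has("s_init")) preset$medium$initial_saturation <- val("s_init")
  if (has("permeability")) preset$medium$permeability <- val("permeability")
  if (has("pec")) {
    preset$medium$entry_capillary_pressure <- val("pec")
  } else if (any(vapply(c("sigma", "theta", "Rc"), has, logical(1)))) {
    preset$medium$entry_capillary_pressure <-
      entry_capillary_pressure(preset$wetting$surface_tension,
                               preset$wetting$contact_angle,
                               preset$medium$pore_radius)
  }
  preset$closure$entry_pressure <- preset$medium$entry_capillary_pressure
  preset
}

#' Rebuild a preset from a configuration list
#'
#' Inverse of [as_wick_config()]: reconstructs the base preset from the
#' membrane name and `rc_policy`, then applies every stored parameter, so
#' that a preset survives a config round-trip unchanged.
#'
#' @param config A configuration list with at least `membrane`.
#' @return A `wick_preset`.
#' @export
preset_from_config <- function(config) {
  if (is.null(config$membrane)) {
    abort("configuration must name a `membrane`",
          class = "paperwick_validation_error")
  }
  preset <- membrane_preset(config$membrane,
                            rc_policy = config$rc_policy %||% "paper")
  vals <- config[intersect(names(config), wick_config_keys())]
  vals <- vals[!vapply(vals, function(v) length(v) == 1 && is.na(v), logical(1))]
  apply_config_values(preset, vals)
}
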