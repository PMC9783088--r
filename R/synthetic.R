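# Synthetic bench measurements: noisy quantized ruler readings of the
# wicking front, per-segment analyte concentrations, and rheometer
# viscosity series. These emulate the *structure* of real bench
# measurements so every pipeline stage is testable without external data;
# the analyte generator is phenomenological (no capture chemistry is
# modelled).

#' Measurement noise model
#'
#' @param front_sd Additive Gaussian noise s.d. of front readings (m);
#'   default 2 mm, consistent with the 0.1-0.5 cm run-to-run oscillations
#'   of bench readings.
#' @param quantization Rounding grid of front readings (m); default 1 mm
#'   (a millimetre-ruled ruler).
#' @param concentration_cv Coefficient of variation of the multiplicative
#'   lognormal noise on concentrations and viscosities.
#' @param seed Integer seed making generator calls reproducible; `NULL`
#'   uses (and advances) the session RNG.
#' @return A `noise_model` list.
#' @export
noise_model <- function(front_sd = 0.002, quantization = 0.001,
                        concentration_cv = 0.1, seed = NULL) {
  check_number(front_sd, "front_sd", lower = 0)
  check_number(quantization, "quantization", lower = 0)
  check_number(concentration_cv, "concentration_cv", lower = 0)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(list(front_sd = front_sd, quantization = quantization,
                 concentration_cv = concentration_cv, seed = seed),
            class = "noise_model")
}

local_noise_seed <- function(noise, envir) {
  if (!is.null(noise$seed)) withr::local_seed(noise$seed, .local_envir = envir)
}

# mean-1 multiplicative lognormal factors; exactly 1 when cv = 0 so that
# noise-free output is seed-independent
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Synthetic ruler readings of a wicking front
#'
#' Corrupts a true front trace the way a ruler-and-timer measurement does:
#' additive zero-mean Gaussian noise, rounding to the ruler grid, clamping
#' to the strip.
#'
#' @param trace True trace tibble (`time_s`, `front_m`).
#' @param noise A [noise_model()].
#' @param strip_length Strip length (m) used for clamping.
#' @return A trace tibble with attribute `source = "synthetic"`.
#' @export
synth_front_readings <- function(trace, noise = noise_model(),
                                 strip_length = 0.06) {
  stopifnot(inherits(noise, "noise_model"))
  if (!is.data.frame(trace) || !all(c("time_s", "front_m") %in% names(trace))) {
    abort("`trace` needs columns `time_s` and `front_m`.",
          class = "paperwick_validation_error")
  }
  local_noise_seed(noise, environment())
  x <- trace$front_m + rnorm(nrow(trace), 0, noise$front_sd)
  if (noise$quantization > 0) {
    x <- round(x / noise$quantization) * noise$quantization
  }
  out <- tibble(time_s = trace$time_s,
                front_m = pmin(pmax(x, 0), strip_length))
  attr(out, "source") <- "synthetic"
  out
}

# deterministic per-segment DNA mean profiles (ng/uL, six 1 cm segments):
# plateau over the early segments, a peak segment, then decline. Anchors:
# 400 ng/uL over the first 2 cm for CF4 and Fusion 5; CF4 peaks at
# 700 ng/uL in the 4-5 cm segment (its front stalls at 5 cm); MF1 stays at
# 200 ng/uL through 4 cm and never reaches 400.
.dna_profiles <- list(
  CF4 = c(400, 400, 450, 550, 700, 60),
  Fusion5 = c(400, 400, 450, 550, 650, 300),
  MF1 = c(200, 200, 200, 200, 300, 150)
)

# Relative scalings for analytes other than DNA. These are NOT anchored to
# any printed value (none exists); they only encode the qualitative
# ordering reported: RNA and protein recover best on MF1, RNA slightly
# better from stimulated saliva.
.analyte_scale <- list(
  DNA = c(CF4 = 1, Fusion5 = 1, MF1 = 1),
  RNA = c(CF4 = 0.08, Fusion5 = 0.15, MF1 = 0.25),
  protein = c(CF4 = 0.4, Fusion5 = 0.45, MF1 = 0.6)
)
.saliva_scale <- list(
  DNA = c(stimulated = 1, unstimulated = 1),
  RNA = c(stimulated = 1.1, unstimulated = 0.9),
  protein = c(stimulated = 1, unstimulated = 1)
)

#' Synthetic per-segment analyte concentration profile
#'
#' Deterministic mean concentration per 1 cm strip segment (six segments
#' over the 6 cm strip) multiplied by mean-1 lognormal noise. DNA means are
#' pinned to the reported levels; RNA and protein are DNA-relative scalings
#' encoding only the reported qualitative ordering (unanchored).
#'
#' @param membrane Membrane identifier.
#' @param analyte `"DNA"`, `"RNA"` or `"protein"`.
#' @param saliva_type `"stimulated"` or `"unstimulated"`.
#' @param noise A [noise_model()]; `concentration_cv` and `seed` are used.
#' @return A tibble with columns `segment`, `x_min_m`, `x_max_m`,
#'   `analyte`, `saliva_type`, `concentration_ng_ul`; attribute
#'   `sample_times` lists the observation times (s).
#' @export
synth_analyte_profile <- function(membrane,
                                  analyte = c("DNA", "RNA", "protein"),
                                  saliva_type = c("stimulated", "unstimulated"),
                                  noise = noise_model()) {
  canonical <- normalize_membrane(membrane)
  analyte <- match.arg(analyte)
  saliva_type <- match.arg(saliva_type)
  stopifnot(inherits(noise, "noise_model"))
  means <- .dna_profiles[[canonical]] *
    .analyte_scale[[analyte]][[canonical]] *
    .saliva_scale[[analyte]][[saliva_type]]
  local_noise_seed(noise, environment())
  conc <- means * lognormal_factors(length(means), noise$concentration_cv)
  edges <- seq(0, 0.06, by = 0.01)
  out <- tibble(segment = seq_along(means),
                x_min_m = edges[-length(edges)],
                x_max_m = edges[-1],
                analyte = analyte, saliva_type = saliva_type,
                concentration_ng_ul = pmax(conc, 0))
  attr(out, "sample_times") <- c(20, 40, 60, 120, 180, 240)
  out
}

#' Synthetic saliva viscosity series
#'
#' Emulates a rheometer run of 21 points (one per minute): stimulated
#' saliva around 2 mPa s, unstimulated around 2.34 mPa s, with mean-1
#' multiplicative lognormal noise.
#'
#' @param saliva_type `"stimulated"` or `"unstimulated"`.
#' @param noise A [noise_model()].
#' @param n_points Number of points (default 21).
#' @return A tibble with columns `point`, `time_min`, `viscosity_pa_s`.
#' @export
synth_viscosity_series <- function(saliva_type = c("stimulated", "unstimulated"),
                                   noise = noise_model(),
                                   n_points = 21) {
  saliva_type <- match.arg(saliva_type)
  stopifnot(inherits(noise, "noise_model"))
  check_number(n_points, "n_points", lower = 1)
  mu <- switch(saliva_type, stimulated = 0.002, unstimulated = 0.00234)
  local_noise_seed(noise, environment())
  visc <- mu * lognormal_factors(n_points, noise$concentration_cv)
  tibble(point = seq_len(n_points), time_min = seq_len(n_points) - 1,
         viscosity_pa_s = visc)
}
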