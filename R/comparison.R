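# Simulation-versus-observation comparison of wicking traces.
#
# The observed front positions shipped with the package are the bench
# measurements reported in running text for the three membranes: 2, 3 and
# 4 cm at 20, 40 and 60 s, 5 cm at 180 s (CF4 and Fusion 5; CF4 stalls
# there and never reaches the strip end) and 6 cm at 240 s (Fusion 5 and
# MF1). Figure-only values are deliberately not transcribed.

#' Observed wicking trace for a membrane
#'
#' Loads the shipped ruler-and-timer front observations for one membrane
#' from the package's plain-text fixtures.
#'
#' @param membrane Membrane identifier (case-insensitive).
#' @return A wicking trace tibble (`time_s`, `front_m`) with attribute
#'   `source = "observed"`.
#' @export
observed_front_trace <- function(membrane) {
  canonical <- normalize_membrane(membrane)
  path <- system.file("extdata",
                      sprintf("observed_front_%s.csv", tolower(canonical)),
                      package = "paperwick", mustWork = TRUE)
  out <- read_trace(path)
  attr(out, "source") <- "observed"
  attr(out, "membrane") <- canonical
  out
}

#' Interpolate a wicking trace at new times
#'
#' Linear interpolation of every value column, exact at the knots.
#' Extrapolation beyond the trace's time span is refused.
#'
#' @param trace A trace tibble with a `time_s` column.
#' @param times Target times (s), all within `range(trace$time_s)`.
#' @return A trace tibble at `times`.
#' @export
interpolate_at <- function(trace, times) {
  if (!is.data.frame(trace) || !"time_s" %in% names(trace)) {
    abort("`trace` must have a `time_s` column.",
          class = "paperwick_validation_error")
  }
  if (any(times < min(trace$time_s) - 1e-12) ||
      any(times > max(trace$time_s) + 1e-12)) {
    abort(sprintf("requested times outside the trace span [%g, %g] s; extrapolation is refused",
                  min(trace$time_s), max(trace$time_s)),
          class = "paperwick_extrapolation_error")
  }
  cols <- setdiff(names(trace), "time_s")
  out <- tibble(time_s = as.numeric(times))
  for (col in cols) {
    out[[col]] <- approx(trace$time_s, trace[[col]], xout = times,
                         ties = "ordered")$y
  }
  attr(out, "source") <- attr(trace, "source")
  out
}

#' Compare observed and simulated wicking traces
#'
#' Interpolates the simulated trace at the observed times (restricted to
#' the overlap of both supports) and reports RMSE, maximum absolute error
#' and a per-time error table. The verdict is `"pass"` iff every fractional
#' error `|sim - obs| / obs` is within `tolerance`. The error metrics are
#' symmetric in the two traces; the verdict, normalized by the observation,
#' is not.
#'
#' @param observed,simulated Trace tibbles with `time_s`, `front_m` and
#'   optionally `mass_kg`.
#' @param tolerance Fractional tolerance for the verdict (default 0.10,
#'   matching the 0.1-0.5 cm run-to-run scatter of bench front readings on
#'   a 4-6 cm scale).
#' @param membrane Optional membrane label carried into the report.
#' @return A `wick_comparison` object; see [tidy.wick_comparison()] and
#'   [glance.wick_comparison()].
#' @export
compare_traces <- function(observed, simulated, tolerance = 0.1,
                           membrane = attr(observed, "membrane") %||% NA_character_) {
  for (tr in list(observed, simulated)) {
    if (!is.data.frame(tr) || !all(c("time_s", "front_m") %in% names(tr))) {
      abort("Traces need columns `time_s` and `front_m`.",
            class = "paperwick_validation_error")
    }
  }
  check_number(tolerance, "tolerance", lower = 0, strict_lower = TRUE)
  keep <- observed$time_s >= min(simulated$time_s) - 1e-12 &
    observed$time_s <= max(simulated$time_s) + 1e-12
  if (!any(keep)) {
    abort("observed and simulated traces have disjoint time supports",
          class = "paperwick_validation_error")
  }
  if (!all(keep)) {
    warn(sprintf("%d observed point(s) outside the simulated span were dropped",
                 sum(!keep)))
  }
  obs <- observed[keep, , drop = FALSE]
  sim <- interpolate_at(simulated, obs$time_s)
  tab <- tibble(time_s = obs$time_s,
                observed_m = obs$front_m,
                simulated_m = sim$front_m,
                abs_error_m = abs(sim$front_m - obs$front_m),
                frac_error = abs(sim$front_m - obs$front_m) / obs$front_m)
  rmse_mass <- NA_real_
  if (all(c("mass_kg") %in% names(obs)) && "mass_kg" %in% names(sim)) {
    rmse_mass <- sqrt(mean((sim$mass_kg - obs$mass_kg)^2))
  }
  structure(list(membrane = membrane,
                 table = tab,
                 rmse_front = sqrt(mean(tab$abs_error_m^2)),
                 max_abs_error_front = max(tab$abs_error_m),
                 rmse_mass = rmse_mass,
                 tolerance = tolerance,
                 verdict = if (all(tab$frac_error <= tolerance)) "pass" else "fail"),
            class = "wick_comparison")
}

#' @export
print.wick_comparison <- function(x, ...) {
  cat(sprintf("<wick_comparison>%s %d times, RMSE %.3g m, max |err| %.3g m\n",
              if (is.na(x$membrane)) "" else paste0(" ", x$membrane),
              nrow(x$table), x$rmse_front, x$max_abs_error_front))
  cat(sprintf("  verdict: %s at %.0f%% fractional tolerance\n",
              x$verdict, 100 * x$tolerance))
  invisible(x)
}

#' Per-time comparison table
#' @param x A `wick_comparison`.
#' @param ... Unused.
#' @return A tibble with one row per compared time.
#' @export
tidy.wick_comparison <- function(x, ...) x$table

#' One-row comparison summary
#' @param x A `wick_comparison`.
#' @param ... Unused.
#' @return A one-row tibble of the report metrics.
#' @export
glance.wick_comparison <- function(x, ...) {
  tibble(membrane = x$membrane, n = nrow(x$table),
         rmse_front_m = x$rmse_front,
         max_abs_error_front_m = x$max_abs_error_front,
         max_frac_error = max(x$table$frac_error),
         rmse_mass_kg = x$rmse_mass,
         tolerance = x$tolerance, verdict = x$verdict)
}
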