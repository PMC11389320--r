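#' Weir equation: energy expenditure from gas exchange
#'
#' Abbreviated Weir equation without urinary-nitrogen correction,
#' EE (kcal/min) = 3.941 * VO2 + 1.106 * VCO2 with VO2/VCO2 in L/min.
#' The coefficients live in the configuration for auditability.
#'
#' @param vo2 Oxygen uptake, L/min (> 0). Vectorised.
#' @param vco2 Carbon-dioxide output, L/min (> 0).
#' @param config Pipeline configuration.
#' @return Energy expenditure in kcal/min.
#' @export
weir_energy_expenditure <- function(vo2, vco2, config = default_config()) {
  if (any(!is.finite(vo2)) || any(!is.finite(vco2)) ||
      any(vo2 <= 0) || any(vco2 <= 0)) {
    stop("vo2 and vco2 must be positive and finite")
  }
  cc <- config$calorimetry
  cc$weir_vo2 * vo2 + cc$weir_vco2 * vco2
}

#' Flag physiologically implausible breaths
#'
#' Screens the respiratory exchange ratio (VCO2/VO2) against `[0.5, 1.3]`.
#' Implausible breaths are flagged, not dropped.
#'
#' @param breaths Data frame with `vo2_lmin` and `vco2_lmin`.
#' @return Logical vector, `TRUE` where the RER is implausible.
#' @export
flag_implausible_breaths <- function(breaths) {
  rer <- breaths$vco2_lmin / breaths$vo2_lmin
  rer < 0.5 | rer > 1.3
}

#' Steady-state energy expenditure of a condition
#'
#' Averages the Weir-converted energy expenditure of all breaths in the
#' last three minutes of the condition window (half-open
#' `[end - 180, end)`, membership by breath timestamp) and expresses it
#' per kilogram of body mass.
#'
#' @param breaths Data frame with columns `time_s`, `vo2_lmin`,
#'   `vco2_lmin`.
#' @param condition_window Numeric `c(start, end)` of the condition in
#'   seconds; must span at least 180 s.
#' @param mass_kg Body mass (> 0).
#' @param condition_id Optional identifier carried into the result.
#' @param config Pipeline configuration.
#' @return A list of class `"steady_state_ee"` with `ee` (kcal/kg/min),
#'   `n_breaths`, `window`, `condition_id`, and `n_flagged` (RER screen).
#' @export
steady_state_ee <- function(breaths, condition_window, mass_kg,
                            condition_id = NA_character_,
                            config = default_config()) {
  stopifnot(length(condition_window) == 2, mass_kg > 0)
  cc <- config$calorimetry
  wlen <- cc$steady_state_window_s
  if (diff(condition_window) < wlen) {
    stop("condition window must span at least ", wlen, " s")
  }
  w <- c(condition_window[2] - wlen, condition_window[2])
  sel <- breaths$time_s >= w[1] & breaths$time_s < w[2]
  n <- sum(sel)
  if (n < cc$min_breaths) {
    stop("only ", n, " breaths in the steady-state window (need >= ",
         cc$min_breaths, ")")
  }
  ee_abs <- weir_energy_expenditure(breaths$vo2_lmin[sel],
                                    breaths$vco2_lmin[sel], config)
  structure(list(
    condition_id = condition_id,
    ee = mean(ee_abs) / mass_kg,
    n_breaths = n,
    window = w,
    n_flagged = sum(flag_implausible_breaths(breaths[sel, , drop = FALSE]))
  ), class = "steady_state_ee")
}

#' @export
print.steady_state_ee <- function(x, ...) {
  cat(sprintf("<steady-state EE> %.5f kcal/kg/min over [%.0f, %.0f) s (%d breaths)\n",
              x$ee, x$window[1], x$window[2], x$n_breaths))
  invisible(x)
}

#' Read a breath-by-breath CSV file
#'
#' Expects columns `timestamp_s, vo2_lmin, vco2_lmin`.
#'
#' @param path CSV path.
#' @return Data frame with columns `time_s`, `vo2_lmin`, `vco2_lmin`.
#' @export
read_breath_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("timestamp_s", "vo2_lmin", "vco2_lmin")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data.frame(time_s = df$timestamp_s, vo2_lmin = df$vo2_lmin,
             vco2_lmin = df$vco2_lmin)
}
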