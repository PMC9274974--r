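#' AMF field condition
#'
#' @param frequency Drive frequency in kHz.
#' @param amplitude Field amplitude H_0 in kA/m.
#' @return An object of class `field_condition`.
#' @export
field_condition <- function(frequency, amplitude) {
  stopifnot(frequency > 0, amplitude > 0)
  structure(list(frequency = frequency, amplitude = amplitude),
            class = "field_condition")
}

#' Calorimetry trace of a ferrofluid sample
#'
#' Time/temperature record of a ferrofluid sample heated by an alternating
#' magnetic field, with the bookkeeping needed to convert an initial
#' heating slope into specific loss power (SLP).
#'
#' @param times Sample times in s, strictly increasing.
#' @param temperatures Temperatures in deg C.
#' @param field_on_time Time (s) at which the field was switched on.
#' @param solution_mass Ferrofluid solution mass in kg.
#' @param iron_mass Iron mass in the sample in kg.
#' @param solution_heat_capacity Solution specific heat in J/(kg K)
#'   (default: water, 4180).
#' @param condition Optional `field_condition`.
#' @return An object of class `calorimetry_trace`.
#' @export
calorimetry_trace <- function(times, temperatures, field_on_time,
                              solution_mass, iron_mass,
                              solution_heat_capacity = 4180,
                              condition = NULL) {
  stopifnot(length(times) == length(temperatures), all(diff(times) > 0),
            solution_mass > 0, iron_mass > 0, solution_heat_capacity > 0)
  structure(list(times = times, temperatures = temperatures,
                 field_on_time = field_on_time,
                 solution_mass = solution_mass, iron_mass = iron_mass,
                 solution_heat_capacity = solution_heat_capacity,
                 condition = condition),
            class = "calorimetry_trace")
}

ols_slope <- function(x, y) {
  if (length(x) < 2 || var(x) == 0) return(0)
  unname(lm.fit(cbind(1, x), y)$coefficients[2])
}

#' Initial heating slope of a calorimetry trace
#'
#' Ordinary least-squares slope over `[field_on, field_on + window]`, minus
#' the baseline drift slope estimated from the `baseline_window` seconds
#' before field-on (0 when fewer than 2 pre-field samples exist).
#'
#' @param trace A `calorimetry_trace`.
#' @param window Fit window length in s after field-on (default 10).
#' @param baseline_window Drift window length in s before field-on
#'   (default 10).
#' @return Corrected slope in K/s.
#' @export
estimate_slope <- function(trace, window = 10, baseline_window = 10) {
  t0 <- trace$field_on_time
  if (t0 + window > max(trace$times) + 1e-9)
    stop("fit window extends beyond the recorded trace")
  sel <- trace$times >= t0 & trace$times <= t0 + window
  if (sum(sel) < 5) stop("need at least 5 samples in the fit window")
  heat <- ols_slope(trace$times[sel], trace$temperatures[sel])
  pre <- trace$times >= t0 - baseline_window & trace$times < t0
  drift <- if (sum(pre) >= 2)
    ols_slope(trace$times[pre], trace$temperatures[pre]) else 0
  heat - drift
}

#' Specific loss power from a heating slope
#'
#' `SLP = C_solution * m_solution * slope / m_iron`, in W per gram of iron
#' when masses are in kg (the kg cancel).
#'
#' @param slope Initial heating slope in K/s.
#' @param trace The `calorimetry_trace` supplying masses and heat capacity.
#' @param window Fit window recorded in the output (s).
#' @return An object of class `slp_estimate`: `slp` (W/g Fe), `slope`,
#'   `fit_window`, `condition`.
#' @export
slp_from_slope <- function(slope, trace, window = NA_real_) {
  stopifnot(is.finite(slope))
  if (trace$iron_mass <= 0) stop("iron mass must be positive")
  slp <- trace$solution_heat_capacity * trace$solution_mass * slope /
    trace$iron_mass / 1000  # W/kg -> W/g
  structure(list(slp = slp, slope = slope, fit_window = window,
                 condition = trace$condition, extrapolated = FALSE),
            class = "slp_estimate")
}

#' @rdname slp_from_slope
#' @export
estimate_slp <- function(trace, window = 10, baseline_window = 10) {
  slope <- estimate_slope(trace, window, baseline_window)
  slp_from_slope(slope, trace, window)
}

#' Linear-response extrapolation of SLP across field conditions
#'
#' Scales an SLP estimate from its measurement condition to a target
#' condition by `(f_target / f_source) * (H_target / H_source)^2`, the
#' linear-response-theory scaling of hysteresis losses. This is a
#' model-based extrapolation (flagged in the result), valid only while the
#' particles stay in the linear response regime.
#'
#' @param est An `slp_estimate` carrying its source `field_condition`.
#' @param target Target `field_condition`.
#' @return An `slp_estimate` at the target condition with
#'   `extrapolated = TRUE`.
#' @export
extrapolate_lrt <- function(est, target) {
  if (is.null(est$condition)) stop("source estimate has no field condition")
  f <- target$frequency / est$condition$frequency
  h <- target$amplitude / est$condition$amplitude
  structure(list(slp = est$slp * f * h^2, slope = est$slope,
                 fit_window = est$fit_window, condition = target,
                 source_condition = est$condition,
                 scale_factor = f * h^2, extrapolated = TRUE),
            class = "slp_estimate")
}
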