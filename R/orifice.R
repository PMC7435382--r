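#' Ideal-orifice environment
#'
#' Physical constants for the ideal pressure-flow model of a mask chamber
#' venting through an orifice: the air inside the chamber at pressure `P`
#' is pushed through an opening of area `S` against atmospheric pressure,
#' and in the frictionless limit the outflow speed follows Bernoulli's
#' relation `u = sqrt(2 (P - Patmos) / rho)`.
#'
#' Defaults are standard sea-level conditions at 15 degC and the sensing
#' surface of the reference spirometer used for calibration.
#'
#' @param atmospheric_pressure Atmospheric pressure `Patmos` in Pa.
#' @param air_density Air density `rho` in kg/m^3.
#' @param orifice_area Orifice cross-section `S` in m^2.
#' @return An object of class `orifice_environment`.
#' @examples
#' env <- orifice_environment()
#' ideal_flow_from_pressure(env$atmospheric_pressure + 100, env)
#' @export
orifice_environment <- function(atmospheric_pressure = 101325,
                                air_density = 1.225,
                                orifice_area = 2.826e-3) {
  for (nm in c("atmospheric_pressure", "air_density", "orifice_area")) {
    v <- get(nm)
    assert_finite(v, nm)
    if (length(v) != 1L || v <= 0) {
      stop(sprintf("`%s` must be a single strictly positive number", nm), call. = FALSE)
    }
  }
  structure(
    list(atmospheric_pressure = atmospheric_pressure,
         air_density = air_density,
         orifice_area = orifice_area),
    class = "orifice_environment"
  )
}

#' @export
print.orifice_environment <- function(x, ...) {
  cat("<orifice_environment>\n")
  cat(sprintf("  Patmos: %g Pa | rho: %g kg/m^3 | S: %g m^2\n",
              x$atmospheric_pressure, x$air_density, x$orifice_area))
  invisible(x)
}

#' Ideal orifice flow from chamber pressure
#'
#' Signed volumetric flow through the orifice for a given chamber pressure,
#' `F = sign(dP) * S * sqrt(2 |dP| / rho)` with `dP = P - Patmos`. Positive
#' flow is outflow (expiration). The relation is odd in `dP`, continuous,
#' and monotone non-decreasing in chamber pressure.
#'
#' @param chamber_pressure Pressure inside the chamber, Pa (vectorised).
#' @param env An [orifice_environment()].
#' @return Flow in m^3/s (multiply by 1000 for L/s).
#' @examples
#' ideal_flow_from_pressure(101425) # ~0.0361 m^3/s
#' @export
ideal_flow_from_pressure <- function(chamber_pressure, env = orifice_environment()) {
  stopifnot(inherits(env, "orifice_environment"))
  assert_finite(chamber_pressure, "chamber_pressure")
  dp <- chamber_pressure - env$atmospheric_pressure
  sign(dp) * env$orifice_area * sqrt(2 * abs(dp) / env$air_density)
}

#' Ideal chamber pressure from flow
#'
#' Algebraic inverse of [ideal_flow_from_pressure()]:
#' `P = Patmos + sign(F) * rho * (F / S)^2 / 2`. The round trip reproduces
#' the flow to machine precision; the simulator uses this to turn a
#' ground-truth flow into a chamber pressure.
#'
#' @param flow Signed flow in m^3/s (positive = outflow, vectorised).
#' @inheritParams ideal_flow_from_pressure
#' @return Chamber pressure in Pa.
#' @export
ideal_pressure_from_flow <- function(flow, env = orifice_environment()) {
  stopifnot(inherits(env, "orifice_environment"))
  assert_finite(flow, "flow")
  env$atmospheric_pressure +
    sign(flow) * env$air_density * (flow / env$orifice_area)^2 / 2
}

#' Standard-condition closed-form flow in L/s
#'
#' The printed closed form of the ideal model under standard sea-level
#' conditions: `F = +coefficient * sqrt(P - Patmos)` L/s for `P > Patmos`
#' and `F = -coefficient * sqrt(Patmos - P)` L/s for `P < Patmos`, with
#' `F = 0` at `P = Patmos` (defined by continuity). The default coefficient
#' 2.9 is kept exactly as printed in the source model; note it is not the
#' value re-derived from the default orifice area and air density
#' (`1000 * S * sqrt(2 / rho)` is about 3.61) -- see the package vignette.
#'
#' @param chamber_pressure Chamber pressure in Pa (vectorised).
#' @param coefficient Closed-form coefficient in L s^-1 Pa^-1/2.
#' @param atmospheric_pressure Atmospheric pressure in Pa.
#' @return Flow in L/s.
#' @examples
#' standard_flow_lps(101326) # 2.9
#' standard_flow_lps(101324) # -2.9
#' @export
standard_flow_lps <- function(chamber_pressure, coefficient = 2.9,
                              atmospheric_pressure = 101325) {
  assert_finite(chamber_pressure, "chamber_pressure")
  assert_finite(coefficient, "coefficient")
  dp <- chamber_pressure - atmospheric_pressure
  sign(dp) * coefficient * sqrt(abs(dp))
}
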