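# Thermodynamic context: converts membrane voltage to reduced potential.

FARADAY <- 96485      # C/mol
GAS_CONST <- 8.314    # J/(mol K)

#' Thermodynamic context for voltage-dependent gating
#'
#' Bundles the recording temperature with the derived reduced-potential scale
#' \eqn{F/(RT)} used by all voltage-dependent model functions. The default of
#' 22 °C (295.15 K) is a typical room temperature for two-electrode
#' voltage-clamp recordings from *Xenopus* oocytes.
#'
#' @param temperature_K Absolute temperature in kelvin (> 0).
#'
#' @return An object of class `thermo_context` with fields `temperature_K`
#'   and `vt_factor` (\eqn{F/(RT)}, in 1/volt).
#' @examples
#' ctx <- thermo_context()
#' ctx$vt_factor # about 39.3 V^-1 at 22 degrees C
#' @export
thermo_context <- function(temperature_K = 295.15) {
  check_number(temperature_K, "temperature_K")
  stop_if(temperature_K <= 0, "temperature_K must be > 0")
  structure(
    list(temperature_K = temperature_K,
         vt_factor = FARADAY / (GAS_CONST * temperature_K)),
    class = "thermo_context")
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf("<thermo_context> T = %.2f K (F/RT = %.4f 1/V)\n",
              x$temperature_K, x$vt_factor))
  invisible(x)
}

#' Reduced membrane potential
#'
#' Converts a membrane voltage in millivolts to the dimensionless reduced
#' potential \eqn{FV/(RT)} that enters the exponential voltage dependence of
#' the gating equilibrium constants.
#'
#' @param V_mV Membrane voltage(s) in millivolts; must be finite.
#' @param ctx A [thermo_context()].
#'
#' @return Dimensionless reduced potential, same length as `V_mV`.
#' @examples
#' reduced_potential(25.42, thermo_context(295.15)) # ~ 1
#' @export
reduced_potential <- function(V_mV, ctx = thermo_context()) {
  stopifnot(inherits(ctx, "thermo_context"))
  stop_if(!is.numeric(V_mV) || any(!is.finite(V_mV)),
          "V_mV must be finite numeric")
  (V_mV / 1000) * ctx$vt_factor
}
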