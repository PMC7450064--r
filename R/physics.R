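#' Physical parameters for force calibration
#'
#' Bundles the Boltzmann constant with the absolute temperature. The thermal
#' energy \eqn{k_B T} converts the drift-to-diffusion ratio of a tracked
#' particle into a force: \eqn{F = k_B T \, v_x / D}.
#'
#' @param temperature_K Absolute temperature in kelvin. Defaults to 298 K
#'   (room temperature).
#'
#' @return An object of class `physical_params` with fields `k_B` (J/K) and
#'   `T` (K).
#' @examples
#' phys <- physical_params()
#' phys$k_B * phys$T  # thermal energy in J, ~4.11e-21 at 298 K
#' @export
physical_params <- function(temperature_K = 298) {
  stopifnot(is.numeric(temperature_K), length(temperature_K) == 1L,
            is.finite(temperature_K), temperature_K > 0)
  structure(list(k_B = 1.380649e-23, T = temperature_K),
            class = "physical_params")
}

#' Thermal energy in femtonewton-micrometres
#'
#' \eqn{k_B T} expressed in fN um (1 J = 1e21 fN um), the natural unit when
#' velocities are in um/s, diffusion coefficients in um^2/s and forces in fN.
#'
#' @param phys A [physical_params()] object.
#' @return Thermal energy in fN um (about 4.11 at 298 K).
#' @export
kBT_fN_um <- function(phys) {
  stopifnot(inherits(phys, "physical_params"))
  phys$k_B * phys$T * 1e21
}
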