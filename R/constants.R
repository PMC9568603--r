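#' Physical constants and unit conventions
#'
#' All quantities in the package use one coherent unit system:
#' lengths in micrometers (um), times in seconds (s), forces in piconewtons
#' (pN), stiffness in pN/um, frequencies in Hz, absolute temperature in K.
#' In these units the Boltzmann constant is `kB = 1.380649e-5` pN um / K and
#' a dynamic viscosity expressed in Pa s is numerically identical in
#' pN s / um^2 (1 Pa s = 1 pN s/um^2), so water-like media are ~1e-3.
#'
#' @format `kB` is a length-one numeric (pN um / K).
#' @export
kB <- 1.380649e-5

# Stokes drag of a sphere: gamma = 6 pi eta a   [pN s / um]
stokes_drag <- function(radius, viscosity) {
  6 * pi * viscosity * radius
}
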