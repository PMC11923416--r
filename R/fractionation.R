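#' Equilibrium liquid-vapor 2H fractionation
#'
#' Horita & Wesolowski (1994) polynomial for the equilibrium fractionation
#' factor between liquid water and vapor for 2H/1H:
#' \deqn{10^3 \ln\alpha^+ = 1158.8\,(T^3/10^9) - 1620.1\,(T^2/10^6)
#'   + 794.84\,(T/10^3) - 161.04 + 2.9992\,(10^9/T^3)}
#' with `T` in kelvin. The per-mil enrichment is
#' `eps_plus = (alpha_plus - 1) * 1000`; it is strictly decreasing in
#' temperature over the biological range accepted here (-10 to 50 degrees C).
#'
#' @param temp_c Temperature, degrees C, in \[-10, 50\].
#' @return Equilibrium enrichment `eps_plus` of liquid over vapor, per mil.
#' @examples
#' equilibrium_fractionation(25)  # ~79 per mil
#' @export
equilibrium_fractionation <- function(temp_c) {
  if (any(temp_c < -10 | temp_c > 50, na.rm = TRUE)) {
    stop("temperature outside the supported range [-10, 50] degrees C")
  }
  tk <- temp_c + 273.15
  ln_alpha <- (1158.8 * tk^3 / 1e9 - 1620.1 * tk^2 / 1e6 +
                 794.84 * tk / 1e3 - 161.04 + 2.9992 * 1e9 / tk^3) / 1000
  (exp(ln_alpha) - 1) * 1000
}

#' Kinetic 2H fractionation for stomatal + boundary-layer diffusion
#'
#' Conductance-weighted kinetic enrichment
#' `eps_k = (eps_s / g_s + eps_b / g_b) / (1/g_s + 1/g_b)`, with the
#' molecular-diffusion value `eps_s = 25` per mil (Merlivat 1978 HDO/H2O
#' diffusivity ratio) through stomata and the 2/3-power boundary-layer value
#' `eps_b = 17` per mil. Defaults are package constants, not field
#' measurements, and can be overridden.
#'
#' @param g_s Stomatal (or total leaf) conductance, mol m-2 s-1.
#' @param g_b Boundary-layer conductance, mol m-2 s-1; default 2.4, the
#'   midpoint of the 2-2.84 range reported for *Pinus*.
#' @param eps_s,eps_b Kinetic enrichments for stomatal and boundary-layer
#'   paths, per mil.
#' @return Kinetic enrichment `eps_k`, per mil.
#' @export
kinetic_fractionation <- function(g_s, g_b = 2.4, eps_s = 25, eps_b = 17) {
  stopifnot(all(g_s > 0), all(g_b > 0))
  (eps_s / g_s + eps_b / g_b) / (1 / g_s + 1 / g_b)
}

#' Temperature-dependent diffusivity of HDO in liquid water
#'
#' Arrhenius form anchored at `D = 2.34e-9` m2 s-1 at 25 degrees C with an
#' activation energy of 19 kJ mol-1 (typical of liquid-water self-diffusion).
#'
#' @param temp_c Water temperature, degrees C.
#' @return Diffusivity, m2 s-1.
#' @export
hdo_diffusivity <- function(temp_c) {
  tk <- temp_c + 273.15
  2.34e-9 * exp(-19000 / 8.3145 * (1 / tk - 1 / 298.15))
}

# Molar density of liquid water, mol m-3
WATER_MOLAR_DENSITY <- 5.55e4
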