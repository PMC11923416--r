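#' Saturation vapor pressure of water
#'
#' Magnus-type formula of Alduchov & Eskridge (1996):
#' `e_sat = 0.61094 * exp(17.625 * T / (T + 243.04))` kPa, with `T` in degrees
#' Celsius. This single formulation is used everywhere in the package
#' (synthetic generator, conductance, leaf-water model) so that `e_i` and
#' `e_a` are mutually consistent.
#'
#' @param temp_c Air or leaf temperature, degrees C.
#' @return Saturation vapor pressure, kPa.
#' @examples
#' e_sat(20)   # ~2.34 kPa
#' @export
e_sat <- function(temp_c) {
  stopifnot(is.numeric(temp_c))
  0.61094 * exp(17.625 * temp_c / (temp_c + 243.04))
}

#' Leaf intercellular vapor pressure
#'
#' The intercellular air space is assumed saturated at leaf temperature; by
#' default leaf temperature is taken equal to air temperature (a coarse-scale
#' assumption appropriate for well-coupled conifer shoots), with an optional
#' additive offset.
#'
#' @param t_leaf Leaf temperature, degrees C.
#' @param offset Additive leaf-minus-air temperature offset, degrees C
#'   (default 0); pass air temperature as `t_leaf` and the offset here.
#' @return `e_i`, kPa.
#' @export
leaf_intercellular_vapor <- function(t_leaf, offset = 0) {
  e_sat(t_leaf + offset)
}

#' Ambient vapor pressure from relative humidity
#'
#' @param rh Relative humidity, percent (0-100).
#' @param temp_c Air temperature, degrees C.
#' @return `e_a = RH/100 * e_sat(T)`, kPa.
#' @export
ambient_vapor <- function(rh, temp_c) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("relative humidity must lie in [0, 100] %")
  }
  rh / 100 * e_sat(temp_c)
}
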