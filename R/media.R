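#' Acoustic medium
#'
#' A homogeneous medium characterized by the three quantities the pulse-echo
#' model needs: density, speed of sound, and the (narrowband) attenuation
#' coefficient at the carrier frequency.
#'
#' @param name Character label.
#' @param density Mass density in kg/m^3; must be positive.
#' @param speed_of_sound Longitudinal speed of sound in m/s; must be positive.
#' @param attenuation Amplitude attenuation coefficient in Np/m at the
#'   carrier frequency; must be non-negative. The package treats attenuation
#'   as a single narrowband value (no frequency dependence).
#'
#' @return An object of class `acoustic_medium`.
#' @examples
#' plexiglas()
#' acoustic_medium("ringer", 998.2, 1483.5, attenuation = 2)
#' @export
acoustic_medium <- function(name, density, speed_of_sound, attenuation = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("'density' must be a single positive number (kg/m^3)")
  }
  if (!is.numeric(speed_of_sound) || length(speed_of_sound) != 1L ||
      !is.finite(speed_of_sound) || speed_of_sound <= 0) {
    stop("'speed_of_sound' must be a single positive number (m/s)")
  }
  if (!is.numeric(attenuation) || length(attenuation) != 1L ||
      !is.finite(attenuation) || attenuation < 0) {
    stop("'attenuation' must be a single non-negative number (Np/m)")
  }
  structure(
    list(name = name, density = density, speed_of_sound = speed_of_sound,
         attenuation = attenuation),
    class = "acoustic_medium"
  )
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf(
    "<acoustic_medium> %s: rho = %.4g kg/m^3, c = %.6g m/s, alpha = %.4g Np/m\n",
    x$name, x$density, x$speed_of_sound, x$attenuation))
  invisible(x)
}

#' Density of water at 20 degrees Celsius
#'
#' 998.2 kg/m^3, from standard reference tables (CRC Handbook); used for the
#' buffer--water impedance in the reference calibration.
#' @export
WATER_DENSITY_20C <- 998.2

#' Plexiglas (PMMA) buffer/reflector medium
#'
#' The buffer rod and reflector latches of the measurement cell: density
#' 1.17 g/cm^3 and longitudinal speed 2760 m/s at 20 degC.
#'
#' @param attenuation Attenuation coefficient of the Plexiglas in Np/m at the
#'   carrier. No validated value is available; the default 25 Np/m is an
#'   order-of-magnitude figure for PMMA near 2 MHz and is documented as
#'   unvalidated. The water-reference calibration makes the analysis
#'   invariant to it (only the product `A0 * exp(-2 * alpha_B * d_B)` enters).
#' @return An `acoustic_medium`.
#' @export
plexiglas <- function(attenuation = 25) {
  acoustic_medium("plexiglas", density = 1170, speed_of_sound = 2760,
                  attenuation = attenuation)
}

#' Water as an acoustic medium
#'
#' Speed of sound from the Marczak polynomial at the given temperature;
#' density fixed at the 20 degC table value (the calibration is performed at
#' 20 +/- 0.5 degC, over which the density variation is negligible for
#' impedance purposes).
#'
#' @param temperature Temperature in degC.
#' @param attenuation Attenuation in Np/m at the carrier (default 0.1,
#'   approximately pure water at 2 MHz).
#' @param poly A [marczak_polynomial()].
#' @return An `acoustic_medium`.
#' @export
water_medium <- function(temperature = 20, attenuation = 0.1,
                         poly = marczak_polynomial()) {
  acoustic_medium("water", density = WATER_DENSITY_20C,
                  speed_of_sound = water_speed_of_sound(temperature, poly),
                  attenuation = attenuation)
}

#' Vessel geometry of the pulse-echo cell
#'
#' @param sample_path_diameter One-way sample path `d` in m (the vessel
#'   diameter); the acoustic propagation distance through the sample is `2*d`.
#' @param buffer_diameter Buffer-rod diameter `d_B` in m.
#' @param buffer_attenuation Buffer attenuation `alpha_B` in Np/m.
#' @return An object of class `vessel_geometry`.
#' @examples
#' default_geometry()
#' @export
vessel_geometry <- function(sample_path_diameter, buffer_diameter,
                            buffer_attenuation) {
  vals <- c(sample_path_diameter, buffer_diameter, buffer_attenuation)
  if (!is.numeric(vals) || length(vals) != 3L || any(!is.finite(vals)) ||
      any(vals <= 0)) {
    stop("all vessel_geometry fields must be single positive finite numbers")
  }
  structure(
    list(sample_path_diameter = sample_path_diameter,
         buffer_diameter = buffer_diameter,
         buffer_attenuation = buffer_attenuation),
    class = "vessel_geometry"
  )
}

#' Default vessel geometry
#'
#' The measurement cell of the study: vessel diameter 37.5 mm, buffer-rod
#' diameter 17 mm, with the (unvalidated) default buffer attenuation.
#' @param buffer_attenuation Buffer attenuation in Np/m.
#' @return A `vessel_geometry`.
#' @export
default_geometry <- function(buffer_attenuation = 25) {
  vessel_geometry(0.0375, 0.017, buffer_attenuation)
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf(
    "<vessel_geometry> d = %.4g mm, d_B = %.4g mm, alpha_B = %.4g Np/m\n",
    1000 * x$sample_path_diameter, 1000 * x$buffer_diameter,
    x$buffer_attenuation))
  invisible(x)
}

#' Temperature polynomial for the speed of sound in pure water
#'
#' Fifth-order polynomial of Marczak (1997, J. Acoust. Soc. Am. 102(5),
#' 2776--2779) giving the speed of sound in pure water as a function of
#' temperature, valid on 0--95 degC.
#'
#' @param coefficients Six polynomial coefficients a0..a5 (m/s per degC^i).
#' @param valid_range Two-element numeric validity interval in degC.
#' @return An object of class `marczak_polynomial`.
#' @examples
#' water_speed_of_sound(20)  # ~1482.38 m/s
#' @export
marczak_polynomial <- function(coefficients = c(1.402385e3, 5.038813,
                                                -5.799136e-2, 3.287156e-4,
                                                -1.398845e-6, 2.787860e-9),
                               valid_range = c(0, 95)) {
  if (length(coefficients) != 6L || !is.numeric(coefficients) ||
      any(!is.finite(coefficients))) {
    stop("'coefficients' must be exactly six finite numbers")
  }
  if (length(valid_range) != 2L || valid_range[1] >= valid_range[2]) {
    stop("'valid_range' must be an increasing interval")
  }
  structure(list(coefficients = coefficients, valid_range = valid_range),
            class = "marczak_polynomial")
}

#' Speed of sound in water at a given temperature
#'
#' Evaluates the fifth-order temperature polynomial. Temperatures outside the
#' polynomial's validity range are an error, not an extrapolation.
#'
#' @param temperature Temperature in degC, scalar.
#' @param poly A [marczak_polynomial()].
#' @return Speed of sound in m/s.
#' @export
water_speed_of_sound <- function(temperature, poly = marczak_polynomial()) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature)) {
    stop("'temperature' must be a single finite number (degC)")
  }
  if (temperature < poly$valid_range[1] || temperature > poly$valid_range[2]) {
    stop(sprintf(
      "temperature %.2f degC outside polynomial validity range [%g, %g]",
      temperature, poly$valid_range[1], poly$valid_range[2]))
  }
  sum(poly$coefficients * temperature^(0:5))
}
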