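#' Acoustic impedance of a medium
#'
#' Z = rho * c, the specific acoustic impedance that governs reflection at
#' interfaces.
#'
#' @param medium An [acoustic_medium()].
#' @return Impedance in Pa.s/m (rayl).
#' @examples
#' acoustic_impedance(plexiglas())  # 3.2292e6 Pa.s/m
#' @export
acoustic_impedance <- function(medium) {
  stopifnot(inherits(medium, "acoustic_medium"))
  medium$density * medium$speed_of_sound
}

#' Pressure reflection coefficient at a plane interface
#'
#' Signed reflection coefficient for a wave travelling from `from_medium`
#' into `to_medium`:
#' R = (Z2 - Z1) / (Z2 + Z1).
#' A negative value means the reflected wave is phase-inverted (180 degree
#' phase shift), as happens at the buffer--suspension interface where the
#' sample impedance is below the buffer impedance.
#'
#' @param from_medium,to_medium [acoustic_medium()] objects on the incident
#'   and far side of the interface.
#' @return Signed dimensionless reflection coefficient, |R| < 1 for distinct
#'   finite impedances.
#' @examples
#' reflection_coefficient(plexiglas(), water_medium(20))  # ~ -0.3715
#' @export
reflection_coefficient <- function(from_medium, to_medium) {
  z1 <- acoustic_impedance(from_medium)
  z2 <- acoustic_impedance(to_medium)
  (z2 - z1) / (z2 + z1)
}

#' Two-way pressure transmission factor through an interface
#'
#' The factor `1 - R12^2` that multiplies the second-echo amplitude: the
#' product of the forward and backward transmission coefficients
#' T12 * T21 = (2*Z2/(Z1+Z2)) * (2*Z1/(Z1+Z2)).
#'
#' @param R12 Signed reflection coefficient, |R12| <= 1.
#' @return Factor in `[0, 1]`.
#' @export
two_way_transmission_factor <- function(R12) {
  if (!is.numeric(R12) || length(R12) != 1L || !is.finite(R12) ||
      abs(R12) > 1) {
    stop("'R12' must be a single number with |R12| <= 1")
  }
  1 - R12^2
}

#' Speed of sound from time of flight
#'
#' c = 2d / TOF: the pulse crosses the sample path twice.
#'
#' @param tof Time of flight in s, positive.
#' @param d One-way sample path in m, positive.
#' @return Speed in m/s.
#' @export
speed_from_tof <- function(tof, d) {
  if (!is.numeric(tof) || any(!is.finite(tof)) || any(tof <= 0)) {
    stop("'tof' must be positive")
  }
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("'d' must be a single positive number")
  }
  2 * d / tof
}

#' Vessel diameter from a water reference measurement
#'
#' d = TOF_w * c_w(T) / 2, using the known temperature-dependent speed of
#' sound in water to turn a measured reference time of flight into the
#' one-way sample path length.
#'
#' @param tof_w Measured time of flight in water, s.
#' @param temperature Reference temperature in degC.
#' @param poly A [marczak_polynomial()].
#' @return Diameter d in m.
#' @export
diameter_from_water_reference <- function(tof_w, temperature = 20,
                                          poly = marczak_polynomial()) {
  if (!is.numeric(tof_w) || length(tof_w) != 1L || !is.finite(tof_w) ||
      tof_w <= 0) {
    stop("'tof_w' must be a single positive number")
  }
  tof_w * water_speed_of_sound(temperature, poly) / 2
}

#' Amplitude constant from the water reference
#'
#' The first-echo amplitude satisfies A1 = C0 * R12 where
#' C0 = A0 * exp(-2*alpha_B*d_B) collects the (constant) excitation amplitude
#' and buffer attenuation. A water reference with known R12 therefore gives
#' C0 = A1_water / R12 without requiring alpha_B or A0 individually.
#'
#' Sign convention: `A1_water_signed` is the signed first-echo amplitude,
#' negative for an aqueous sample against a Plexiglas buffer (phase-inverting
#' interface, R12 < 0). A non-positive C0 signals a sign-convention violation
#' and is an error.
#'
#' @param A1_water_signed Signed first-echo amplitude of the water reference.
#' @param R12_water Signed buffer--water reflection coefficient, nonzero.
#' @return C0 > 0, in the amplitude units of the recording.
#' @export
calibrate_C0 <- function(A1_water_signed, R12_water) {
  if (!is.numeric(R12_water) || length(R12_water) != 1L ||
      !is.finite(R12_water) || R12_water == 0) {
    stop("'R12_water' must be a single nonzero number")
  }
  if (!is.numeric(A1_water_signed) || length(A1_water_signed) != 1L ||
      !is.finite(A1_water_signed)) {
    stop("'A1_water_signed' must be a single finite number")
  }
  C0 <- A1_water_signed / R12_water
  if (C0 <= 0) {
    stop("C0 <= 0: sign of A1 inconsistent with sign of R12 ",
         "(sign-convention violation)")
  }
  C0
}

#' Attenuation coefficient from echo amplitudes
#'
#' The calibrated narrowband estimator
#' alpha = (1 / (2d)) * ln( -A1 * (1 - (A1/C0)^2) / A2 ),
#' obtained by eliminating the interface reflection coefficient through
#' R12 = A1 / C0. It assumes the reflector is made of the same material as
#' the buffer (R23 = -R12); see [attenuation_general()] for the general
#' two-interface form.
#'
#' @param A1_signed Signed first-echo amplitude (negative for an aqueous
#'   sample against a Plexiglas buffer).
#' @param A2 Second-echo amplitude magnitude, positive.
#' @param C0 Calibration amplitude constant from [calibrate_C0()].
#' @param d One-way sample path in m.
#' @return Attenuation coefficient alpha in Np/m.
#' @examples
#' # zero-attenuation fixed point
#' attenuation_from_amplitudes(-0.3715, 0.3715 * (1 - 0.3715^2), 1, 0.0375)
#' @export
attenuation_from_amplitudes <- function(A1_signed, A2, C0, d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("'d' must be a single positive number")
  }
  if (!is.numeric(A2) || length(A2) != 1L || !is.finite(A2) || A2 <= 0) {
    stop("'A2' must be a single positive amplitude magnitude")
  }
  if (!is.numeric(C0) || length(C0) != 1L || !is.finite(C0) || C0 == 0) {
    stop("'C0' must be a single nonzero number")
  }
  arg <- -A1_signed * (1 - (A1_signed / C0)^2) / A2
  if (!is.finite(arg) || arg <= 0) {
    stop("non-positive log argument in attenuation estimator: ",
         "sign convention or calibration failure")
  }
  log(arg) / (2 * d)
}

#' General two-interface attenuation estimator
#'
#' Brute-force form without the equal-material assumption: dividing the
#' second-echo amplitude model
#' A2 = C0 * T12 * R23 * T21 * exp(-2*alpha*d) by the first-echo model
#' A1 = C0 * R12 gives
#' alpha = (1 / (2d)) * ln( A1 * (1 - R12^2) * R23 / (A2_signed * R12) ).
#' With a phase-inverting far interface the recorded second echo has sign
#' opposite to the first; `A2_signed` carries that sign. When
#' R23 = -R12 (reflector material equal to buffer material) this reduces to
#' [attenuation_from_amplitudes()] with A2 = |A2_signed|.
#'
#' @param A1_signed Signed first-echo amplitude.
#' @param A2_signed Signed second-echo amplitude.
#' @param R12 Signed buffer--sample reflection coefficient.
#' @param R23 Signed sample--reflector reflection coefficient.
#' @param d One-way sample path in m.
#' @return Attenuation coefficient alpha in Np/m.
#' @export
attenuation_general <- function(A1_signed, A2_signed, R12, R23, d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("'d' must be a single positive number")
  }
  arg <- A1_signed * (1 - R12^2) * R23 / (A2_signed * R12)
  if (!is.finite(arg) || arg <= 0) {
    stop("non-positive log argument in general attenuation estimator")
  }
  log(arg) / (2 * d)
}

#' Convert between nepers and decibels
#'
#' 1 Np = 20/ln(10) dB = 8.6859 dB. Attenuation is carried in Np/m
#' throughout the package; these helpers convert for reporting only.
#'
#' @param x Value in Np (or Np/m).
#' @return Value in dB (or dB/m).
#' @export
np_to_db <- function(x) x * (20 / log(10))

#' @rdname np_to_db
#' @param x_db Value in dB (or dB/m).
#' @export
db_to_np <- function(x_db) x_db / (20 / log(10))
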