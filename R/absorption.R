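## Chamber-absorption module: third-octave band set, band-averaged air
## absorption, and the Sabine-type absorption factors of the empty chamber
## and of introduced wing sets.

SABINE <- 24 * log(10)   # 55.262..., the Sabine constant c*T*A/V relation

#' Preferred third-octave bands in a frequency range
#'
#' Returns the preferred-number third-octave bands whose centre frequencies
#' fall in `[fcLo, fcHi]`.  Centres follow the preferred series
#' (1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8) times a power of ten; band
#' edges are `fc/2^(1/6)` and `fc*2^(1/6)` (base-2) or the base-10 analogue.
#' The default ultrasonic analysis range 20-100 kHz yields 8 bands with
#' centres 20, 25, 31.5, 40, 50, 63, 80 and 100 kHz.
#'
#' @param fcLo,fcHi inclusive limits for band centre frequencies (Hz)
#' @param convention `"base2"` or `"base10"` edge convention
#' @return list of [Band-class] objects in increasing frequency order
#' @examples
#' length(thirdOctaveBands(20e3, 100e3))   # 8
#' @export
thirdOctaveBands <- function(fcLo = 20e3, fcHi = 100e3,
                             convention = c("base2", "base10")) {
  convention <- match.arg(convention)
  stopifnot(fcLo > 0, fcLo <= fcHi)
  pref <- c(1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8)
  decades <- 10^seq(floor(log10(fcLo)) - 1, ceiling(log10(fcHi)))
  centres <- sort(unique(as.vector(outer(pref, decades))))
  centres <- centres[centres >= fcLo * (1 - 1e-9) & centres <= fcHi * (1 + 1e-9)]
  if (!length(centres)) stop("no preferred third-octave centre in range")
  lapply(centres, Band, convention = convention)
}

#' Band-averaged air volume absorption coefficient
#'
#' Classical thermoviscous (Stokes-Kirchhoff) attenuation of sound energy in
#' air, averaged over a third-octave band.  The single-frequency coefficient
#' is \deqn{m(f) = \frac{4\pi^2 f^2}{\rho c^3}\left(\frac{4}{3}\mu +
#' (\gamma - 1)\frac{k}{C_p}\right) \quad (m^{-1}),}
#' and the band value is its mean over `[fl, fh]`,
#' `m1 = (fh^3 - fl^3) / (3 (fh - fl))` times the constant factor.  In the
#' degenerate limit `fh -> fl` this reduces to `m(fl)`.
#'
#' @param band a [Band-class]
#' @param air an [AirProperties-class]
#' @return list with elements `band` and `m1` (m^-1)
#' @export
airAttenuationBand <- function(band, air = AirProperties()) {
  stopifnot(is(band, "Band"), is(air, "AirProperties"))
  const <- 4 * pi^2 / (air@rho * air@c^3) *
    ((4 / 3) * air@mu + (air@gamma - 1) * air@kTh / air@Cp)
  fl <- band@fl; fh <- band@fh
  f2bar <- if (abs(fh - fl) < 1e-12 * fl) fl^2 else (fh^3 - fl^3) / (3 * (fh - fl))
  list(band = band, m1 = const * f2bar)
}

#' Absorption factor of the empty reverberation chamber
#'
#' Sabine-type random-incidence absorption factor with air-attenuation
#' correction:
#' \deqn{\alpha_0 = \frac{55.26\, V}{c\, S\, T_0} - \frac{4 m_1 V}{S},}
#' where `T0` is the spatially averaged reverberation time of the empty
#' chamber and `m1` the band-averaged air volume absorption coefficient.
#'
#' @param chamber a [ChamberSpec-class]
#' @param band a [Band-class]
#' @param T0 a [ReverbMeasurement-class] (or a bare positive number of seconds)
#' @param air an [AirProperties-class]
#' @return absorption factor (dimensionless, not clamped)
#' @export
emptyChamberAlpha <- function(chamber, band, T0, air = AirProperties()) {
  stopifnot(is(chamber, "ChamberSpec"), is(band, "Band"))
  t0 <- if (is(T0, "ReverbMeasurement")) T0@t60 else as.numeric(T0)
  if (!is.finite(t0) || t0 <= 0) stop("T0 must be a positive reverberation time")
  m1 <- airAttenuationBand(band, air)$m1
  SABINE * chamber@V / (air@c * chamber@S * t0) - 4 * m1 * chamber@V / chamber@S
}

#' Absorption factor of an introduced wing set
#'
#' Difference form of the reverberation-room method:
#' \deqn{\alpha_w = \frac{55.26\, V}{c\, S_w}\left(\frac{1}{T_1} -
#'   \frac{1}{T_0}\right),}
#' where `T0` and `T1` are the reverberation times before and after the
#' introduction of the wings and `Sw` their planform area.  The air
#' attenuation term cancels because both measurements are taken under the
#' same air conditions, so `T1 = T0` gives exactly zero.
#'
#' @param chamber a [ChamberSpec-class]
#' @param band a [Band-class]
#' @param T0,T1 [ReverbMeasurement-class] objects (or bare seconds): empty
#'   chamber and with wings
#' @param geom a [WingSetGeometry-class] carrying the wing area `Sw`
#' @param air an [AirProperties-class]
#' @return absorption factor (dimensionless, not clamped)
#' @export
wingAlpha <- function(chamber, band, T0, T1, geom, air = AirProperties()) {
  stopifnot(is(chamber, "ChamberSpec"), is(band, "Band"),
            is(geom, "WingSetGeometry"))
  t0 <- if (is(T0, "ReverbMeasurement")) T0@t60 else as.numeric(T0)
  t1 <- if (is(T1, "ReverbMeasurement")) T1@t60 else as.numeric(T1)
  if (!is.finite(t0) || t0 <= 0 || !is.finite(t1) || t1 <= 0)
    stop("T0 and T1 must be positive reverberation times")
  if (geom@Sw <= 0) stop("wing area Sw must be positive")
  SABINE * chamber@V / (air@c * geom@Sw) * (1 / t1 - 1 / t0)
}

## Inverses used by the synthetic generator: reverberation time implied by a
## target absorption factor (empty chamber), and with-wings time implied by
## a target wing absorption on top of a given T0.
invertEmptyChamberAlpha <- function(chamber, band, alpha0, air = AirProperties()) {
  m1 <- airAttenuationBand(band, air)$m1
  denom <- alpha0 + 4 * m1 * chamber@V / chamber@S
  if (denom <= 0) stop("alpha0 too small: implied T0 not positive and finite")
  SABINE * chamber@V / (air@c * chamber@S * denom)
}

invertWingAlpha <- function(chamber, band, T0, alphaw, Sw, air = AirProperties()) {
  inv <- 1 / T0 + alphaw * Sw * air@c / (SABINE * chamber@V)
  if (inv <= 0) stop("alphaw too large: implied T1 not positive")
  1 / inv
}
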