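#' @import methods
NULL

## ---------------------------------------------------------------------------
## Central S4 classes for the chamber-absorption pipeline.  All times are in
## seconds, frequencies in Hz, SI units throughout; dB levels are 10*log10 of
## energy-like quantities.
## ---------------------------------------------------------------------------

#' One-third-octave analysis band
#'
#' A frequency band with centre `fc` and edges `fl`, `fh`.  Under the base-2
#' convention the edges are `fc / 2^(1/6)` and `fc * 2^(1/6)`, so that
#' `fh/fl = 2^(1/3)`; the base-10 convention uses `10^(1/20)` and ratio
#' `10^(1/10)`.
#'
#' @slot fc centre frequency (Hz)
#' @slot fl lower band-edge frequency (Hz)
#' @slot fh upper band-edge frequency (Hz)
#' @export
setClass("Band", representation(fc = "numeric", fl = "numeric", fh = "numeric"))

setValidity("Band", function(object) {
  if (length(object@fc) != 1L || length(object@fl) != 1L || length(object@fh) != 1L)
    return("fc, fl, fh must be scalars")
  if (!(object@fl > 0 && object@fl < object@fc && object@fc < object@fh))
    return("band edges must satisfy 0 < fl < fc < fh")
  ratio <- object@fh / object@fl
  ok <- abs(ratio / 2^(1/3) - 1) < 1e-6 || abs(ratio / 10^(1/10) - 1) < 1e-6
  if (!ok) return("fh/fl is not a third-octave ratio (base-2 or base-10)")
  TRUE
})

#' Construct a third-octave band around a centre frequency
#'
#' @param fc centre frequency (Hz)
#' @param convention `"base2"` (edges `fc*2^(+-1/6)`) or `"base10"`
#'   (edges `fc*10^(+-1/20)`)
#' @return a [Band-class] object
#' @examples
#' b <- Band(20000)
#' bandEdges(b)
#' @export
Band <- function(fc, convention = c("base2", "base10")) {
  convention <- match.arg(convention)
  half <- if (convention == "base2") 2^(1/6) else 10^(1/20)
  new("Band", fc = as.numeric(fc), fl = fc / half, fh = fc * half)
}

#' Sampled pressure recording
#'
#' A mono pressure waveform in arbitrary linear units, with its sampling
#' frequency, the sound-offset time (when the steady-state excitation was
#' switched off), and a microphone-position label.
#'
#' @slot samples numeric waveform
#' @slot fs sampling frequency (Hz)
#' @slot tauOff sound-offset time (s)
#' @slot positionId microphone position label
#' @export
setClass("Recording",
         representation(samples = "numeric", fs = "numeric",
                        tauOff = "numeric", positionId = "character"))

setValidity("Recording", function(object) {
  if (length(object@samples) < 2L) return("need at least two samples")
  if (object@fs <= 0) return("fs must be positive")
  dur <- length(object@samples) / object@fs
  if (object@tauOff < 0 || object@tauOff >= dur)
    return("tauOff must lie in [0, duration)")
  TRUE
})

#' @rdname Recording-class
#' @param samples numeric waveform
#' @param fs sampling frequency (Hz)
#' @param tauOff sound-offset time (s)
#' @param positionId microphone position label
#' @export
Recording <- function(samples, fs, tauOff = 0, positionId = "pos1") {
  new("Recording", samples = as.numeric(samples), fs = as.numeric(fs),
      tauOff = as.numeric(tauOff), positionId = as.character(positionId))
}

#' Nonnegative signal envelope
#'
#' Magnitude of the analytic signal, possibly smoothed; shares the sampling
#' grid of the recording it came from.
#'
#' @slot values nonnegative envelope samples
#' @slot fs sampling frequency (Hz)
#' @slot tauOff sound-offset time carried over from the recording (s)
#' @export
setClass("EnvelopeCurve",
         representation(values = "numeric", fs = "numeric", tauOff = "numeric"))

setValidity("EnvelopeCurve", function(object) {
  if (any(object@values < 0)) return("envelope values must be nonnegative")
  if (object@fs <= 0) return("fs must be positive")
  TRUE
})

#' Schroeder backward-integrated decay curve
#'
#' Decay level in dB relative to the level at the sound offset, on the sample
#' grid between `tauOff` and the noise-crossing time `tauN`.  `slopeA`
#' (dB/s) and `interceptB` (dB) hold the fitted regression line once
#' [estimateT60()] has been run (NA before that).
#'
#' @slot levelDb decay level (dB, <= 0), non-increasing
#' @slot times time axis (s)
#' @slot tauN noise-crossing time (s)
#' @slot slopeA fitted slope (dB/s)
#' @slot interceptB fitted intercept (dB)
#' @export
setClass("SchroederCurve",
         representation(levelDb = "numeric", times = "numeric", tauN = "numeric",
                        slopeA = "numeric", interceptB = "numeric"))

setValidity("SchroederCurve", function(object) {
  if (length(object@levelDb) != length(object@times))
    return("levelDb and times must have equal length")
  if (any(diff(object@levelDb) > 1e-9)) return("levelDb must be non-increasing")
  if (abs(object@levelDb[1]) > 1e-9) return("levelDb must start at 0 dB")
  if (!is.na(object@slopeA) && object@slopeA >= 0)
    return("fitted slope must be negative")
  TRUE
})

#' Reverberation chamber geometry
#'
#' @slot V chamber volume (m^3)
#' @slot S chamber interior surface area (m^2)
#' @export
setClass("ChamberSpec", representation(V = "numeric", S = "numeric"))

setValidity("ChamberSpec", function(object) {
  if (object@V <= 0 || object@S <= 0) return("V and S must be positive") else TRUE
})

#' @rdname ChamberSpec-class
#' @param V chamber volume (m^3)
#' @param S chamber interior surface area (m^2)
#' @export
ChamberSpec <- function(V, S) new("ChamberSpec", V = as.numeric(V), S = as.numeric(S))

#' Thermophysical properties of the chamber air
#'
#' Defaults are standard values for dry air at 20 degrees C and 70% relative
#' humidity; all overridable.
#'
#' @slot c speed of sound (m/s)
#' @slot mu dynamic viscosity (Pa s)
#' @slot rho density (kg/m^3)
#' @slot gamma ratio of specific heats (-)
#' @slot Pr Prandtl number (-)
#' @slot Cp heat capacity at constant pressure (J/kg/K)
#' @slot kTh thermal conductivity (W/m/K)
#' @slot tempC temperature (degrees C)
#' @slot rh relative humidity (%)
#' @export
setClass("AirProperties",
         representation(c = "numeric", mu = "numeric", rho = "numeric",
                        gamma = "numeric", Pr = "numeric", Cp = "numeric",
                        kTh = "numeric", tempC = "numeric", rh = "numeric"))

setValidity("AirProperties", function(object) {
  vals <- c(object@c, object@mu, object@rho, object@Pr, object@Cp, object@kTh,
            object@rh)
  if (any(vals <= 0)) return("physical quantities must be positive")
  if (object@gamma <= 1) return("gamma must exceed 1")
  TRUE
})

#' @rdname AirProperties-class
#' @param c speed of sound (m/s)
#' @param mu dynamic viscosity (Pa s)
#' @param rho density (kg/m^3)
#' @param gamma ratio of specific heats
#' @param Pr Prandtl number
#' @param Cp heat capacity at constant pressure (J/kg/K)
#' @param kTh thermal conductivity (W/m/K)
#' @param tempC temperature (degrees C)
#' @param rh relative humidity (%)
#' @export
AirProperties <- function(c = 343, mu = 1.81e-5, rho = 1.204, gamma = 1.4,
                          Pr = 0.71, Cp = 1005, kTh = 0.0257,
                          tempC = 20, rh = 70) {
  new("AirProperties", c = c, mu = mu, rho = rho, gamma = gamma, Pr = Pr,
      Cp = Cp, kTh = kTh, tempC = tempC, rh = rh)
}

#' Spatially averaged reverberation time for one band
#'
#' @slot band the analysis [Band-class]
#' @slot t60 reverberation time (s), arithmetic mean over microphone positions
#' @slot nPositions number of microphone positions averaged
#' @export
setClass("ReverbMeasurement",
         representation(band = "Band", t60 = "numeric", nPositions = "integer"))

setValidity("ReverbMeasurement", function(object) {
  if (object@t60 <= 0) return("t60 must be positive")
  if (object@nPositions < 1L) return("nPositions must be >= 1")
  TRUE
})

#' @rdname ReverbMeasurement-class
#' @param band a [Band-class]
#' @param t60 reverberation time (s)
#' @param nPositions number of microphone positions averaged
#' @export
ReverbMeasurement <- function(band, t60, nPositions = 1L)
  new("ReverbMeasurement", band = band, t60 = as.numeric(t60),
      nPositions = as.integer(nPositions))

#' Per-band absorption-factor spectrum
#'
#' Ordered (band, alpha) pairs for one subject: the empty chamber or one
#' wing set.  Absorption factors are not clamped to [0, 1]; values outside
#' the physical range are kept raw (measurement noise can produce them, and
#' clamping would bias spatial averages) and flagged with a warning at
#' construction.
#'
#' @slot bands list of [Band-class] objects
#' @slot alpha absorption factor per band (dimensionless)
#' @slot subjectId set/preparation label
#' @slot kind `"empty-chamber"` or `"wing-set"`
#' @export
setClass("AbsorptionSpectrum",
         representation(bands = "list", alpha = "numeric",
                        subjectId = "character", kind = "character"))

setValidity("AbsorptionSpectrum", function(object) {
  if (length(object@bands) != length(object@alpha))
    return("one alpha per band required")
  if (!all(vapply(object@bands, is, logical(1), "Band")))
    return("bands must be Band objects")
  if (any(!is.finite(object@alpha))) return("alpha entries must be finite")
  if (!object@kind %in% c("empty-chamber", "wing-set"))
    return("kind must be 'empty-chamber' or 'wing-set'")
  TRUE
})

#' @rdname AbsorptionSpectrum-class
#' @param bands list of [Band-class] objects
#' @param alpha absorption factors, one per band
#' @param subjectId set/preparation label
#' @param kind `"empty-chamber"` or `"wing-set"`
#' @export
AbsorptionSpectrum <- function(bands, alpha, subjectId, kind = "wing-set") {
  if (any(alpha < 0 | alpha > 1))
    warning("absorption factor outside [0, 1] kept unclamped for ", subjectId)
  new("AbsorptionSpectrum", bands = bands, alpha = as.numeric(alpha),
      subjectId = as.character(subjectId), kind = kind)
}

#' Wing-set planform geometry
#'
#' @slot Sw wing planform area (m^2)
#' @slot Sb background reference area (m^2)
#' @slot Nw wing pixel count
#' @slot N total pixel count
#' @export
setClass("WingSetGeometry",
         representation(Sw = "numeric", Sb = "numeric",
                        Nw = "numeric", N = "numeric"))

setValidity("WingSetGeometry", function(object) {
  if (object@Nw < 0 || object@Nw > object@N) return("need 0 <= Nw <= N")
  if (object@Sw < 0 || object@Sw > object@Sb) return("need 0 <= Sw <= Sb")
  TRUE
})

#' @rdname WingSetGeometry-class
#' @param Sw wing planform area (m^2)
#' @param Sb background reference area (m^2)
#' @param Nw wing pixel count
#' @param N total pixel count
#' @export
WingSetGeometry <- function(Sw, Sb, Nw = 0, N = 1)
  new("WingSetGeometry", Sw = as.numeric(Sw), Sb = as.numeric(Sb),
      Nw = as.numeric(Nw), N = as.numeric(N))

#' Two-target sonar comparison scenario
#'
#' Parameters of the paired detection-distance comparison: a reference
#' (male) detection distance, the atmospheric attenuation factor at the call
#' frequency, and the two wing absorption factors.  The bat's detection
#' threshold, source level and noise are implicit: they are assumed equal for
#' the two targets and cancel in the comparison.
#'
#' @slot r2 reference (male) detection distance (m)
#' @slot lam atmospheric attenuation factor (dB/m)
#' @slot alpha1 female wing absorption factor (-)
#' @slot alpha2 male wing absorption factor (-)
#' @export
setClass("SonarScenario",
         representation(r2 = "numeric", lam = "numeric",
                        alpha1 = "numeric", alpha2 = "numeric"))

setValidity("SonarScenario", function(object) {
  if (object@r2 <= 0) return("r2 must be positive")
  if (object@lam < 0) return("lam must be nonnegative")
  if (object@alpha1 < 0 || object@alpha1 >= 1 ||
      object@alpha2 < 0 || object@alpha2 >= 1)
    return("absorption factors must lie in [0, 1)")
  TRUE
})

#' @rdname SonarScenario-class
#' @param r2 reference (male) detection distance (m)
#' @param lam atmospheric attenuation factor (dB/m)
#' @param alpha1 female wing absorption factor
#' @param alpha2 male wing absorption factor
#' @export
SonarScenario <- function(r2, lam, alpha1, alpha2)
  new("SonarScenario", r2 = as.numeric(r2), lam = as.numeric(lam),
      alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2))

## ------------------------------- accessors --------------------------------

#' @describeIn Recording-class the waveform
#' @param object,x an object
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @export
setMethod("samples", "Recording", function(object) object@samples)

#' @describeIn Recording-class sampling frequency (Hz)
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))
#' @export
setMethod("sampleRate", "Recording", function(object) object@fs)
#' @export
setMethod("sampleRate", "EnvelopeCurve", function(object) object@fs)

#' @describeIn Recording-class sound-offset time (s)
#' @export
setGeneric("offsetTime", function(object) standardGeneric("offsetTime"))
#' @export
setMethod("offsetTime", "Recording", function(object) object@tauOff)
#' @export
setMethod("offsetTime", "EnvelopeCurve", function(object) object@tauOff)

#' @describeIn Band-class band edges as `c(fl, fh)` (Hz)
#' @export
setGeneric("bandEdges", function(object) standardGeneric("bandEdges"))
#' @export
setMethod("bandEdges", "Band", function(object) c(fl = object@fl, fh = object@fh))

#' @describeIn Band-class centre frequency (Hz)
#' @export
setGeneric("bandCentre", function(object) standardGeneric("bandCentre"))
#' @export
setMethod("bandCentre", "Band", function(object) object@fc)

#' @describeIn ReverbMeasurement-class the reverberation time (s)
#' @export
setGeneric("reverbTime", function(object) standardGeneric("reverbTime"))
#' @export
setMethod("reverbTime", "ReverbMeasurement", function(object) object@t60)

#' @describeIn AbsorptionSpectrum-class absorption factors, named by centre
#'   frequency (Hz)
#' @export
setGeneric("alphaValues", function(object) standardGeneric("alphaValues"))
#' @export
setMethod("alphaValues", "AbsorptionSpectrum", function(object) {
  stats::setNames(object@alpha,
                  vapply(object@bands, bandCentre, numeric(1)))
})

## ----------------------------- show methods -------------------------------

setMethod("show", "Band", function(object) {
  cat(sprintf("Band: fc = %.4g Hz [%.4g, %.4g] Hz\n",
              object@fc, object@fl, object@fh))
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s': %d samples @ %.4g Hz (%.4g s), tauOff = %.4g s\n",
              object@positionId, length(object@samples), object@fs,
              length(object@samples) / object@fs, object@tauOff))
})

setMethod("show", "SchroederCurve", function(object) {
  cat(sprintf("SchroederCurve: %d points, range [%.1f, 0] dB, tauN = %.4g s",
              length(object@levelDb), min(object@levelDb), object@tauN))
  if (!is.na(object@slopeA))
    cat(sprintf(", fitted slope %.4g dB/s", object@slopeA))
  cat("\n")
})

setMethod("show", "AbsorptionSpectrum", function(object) {
  cat(sprintf("AbsorptionSpectrum '%s' (%s), %d bands\n",
              object@subjectId, object@kind, length(object@bands)))
  print(round(alphaValues(object), 4))
})

setMethod("show", "ReverbMeasurement", function(object) {
  cat(sprintf("ReverbMeasurement: T60 = %.4g s at fc = %.4g Hz (n = %d positions)\n",
              object@t60, bandCentre(object@band), object@nPositions))
})
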