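## Reverberation-time estimation from a steady-state decay recording:
## Kaiser FIR third-octave bandpass -> Hilbert envelope + moving-average
## smoothing -> Lundeby-style noise-crossing time -> Schroeder backward
## integration -> linear regression to the -60 dB extrapolation.

#' Kaiser-window FIR bandpass specification
#'
#' @slot band the analysis [Band-class]
#' @slot fs sampling frequency (Hz)
#' @slot stopAttenDb stopband attenuation (dB), >= 80
#' @slot transitionFrac transition width as a fraction of each band edge
#' @export
setClass("FilterSpec",
         representation(band = "Band", fs = "numeric",
                        stopAttenDb = "numeric", transitionFrac = "numeric"))

setValidity("FilterSpec", function(object) {
  if (object@stopAttenDb < 80) return("stopAttenDb must be >= 80")
  if (object@transitionFrac <= 0 || object@transitionFrac >= 0.5)
    return("transitionFrac must lie in (0, 0.5)")
  if (object@band@fh * (1 + object@transitionFrac) >= object@fs / 2)
    return("band edges (plus transition) must lie below Nyquist")
  TRUE
})

#' @rdname FilterSpec-class
#' @param band a [Band-class]
#' @param fs sampling frequency (Hz)
#' @param stopAttenDb stopband attenuation (dB)
#' @param transitionFrac transition width as a fraction of each band edge
#' @export
FilterSpec <- function(band, fs, stopAttenDb = 80, transitionFrac = 0.15)
  new("FilterSpec", band = band, fs = as.numeric(fs),
      stopAttenDb = as.numeric(stopAttenDb),
      transitionFrac = as.numeric(transitionFrac))

## Kaiser design: beta and tap count from the attenuation spec and the
## narrower of the two transition widths.  A 2 dB design margin and a
## halved design transition guard the realised response against the
## approximation error of the empirical order formula (whose nominal
## transition width marks the ripple band, not the point where the target
## attenuation is actually reached), so the achieved stopband attenuation
## meets the spec everywhere outside the stated transition band.
kaiserDesign <- function(fspec) {
  A <- fspec@stopAttenDb + 2
  beta <- if (A > 50) 0.1102 * (A - 8.7)
          else if (A >= 21) 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
          else 0
  df <- fspec@transitionFrac * min(fspec@band@fl, fspec@band@fh)
  dw <- 2 * pi * (df / 2) / fspec@fs
  n <- ceiling((A - 7.95) / (2.285 * dw))
  if (n %% 2 == 1) n <- n + 1          # even order -> odd length, type-I FIR
  ## cutoffs at the middle of each transition band
  wl <- (fspec@band@fl - df / 2) / (fspec@fs / 2)
  wh <- (fspec@band@fh + df / 2) / (fspec@fs / 2)
  h <- signal::fir1(n, c(wl, wh), type = "pass",
                    window = signal::kaiser(n + 1, beta), scale = TRUE)
  as.numeric(h)
}

#' Bandpass-filter a recording into one third-octave band
#'
#' Applies a linear-phase Kaiser-window FIR bandpass passing `[fl, fh]` and
#' attenuating frequencies outside the band by at least `stopAttenDb`
#' (default 80 dB).  The constant group delay of the linear-phase filter is
#' compensated by shifting the output back, so the sound-offset time of the
#' recording is preserved.
#'
#' @param rec a [Recording-class]
#' @param fspec a [FilterSpec-class]; its `fs` must match the recording
#' @return the filtered [Recording-class]
#' @export
bandpassFilter <- function(rec, fspec) {
  stopifnot(is(rec, "Recording"), is(fspec, "FilterSpec"))
  if (abs(rec@fs - fspec@fs) > 1e-9 * rec@fs)
    stop("sampling frequency differs between recording and filter spec")
  h <- kaiserDesign(fspec)
  x <- rec@samples
  y <- signal::fftfilt(h, c(x, numeric(length(h))))
  delay <- (length(h) - 1) / 2
  y <- y[(delay + 1):(delay + length(x))]
  Recording(y, rec@fs, rec@tauOff, rec@positionId)
}

## Frequency response of the designed filter on a dense grid (dB magnitude).
filterResponseDb <- function(fspec, nGrid = 8192) {
  h <- kaiserDesign(fspec)
  f <- seq(0, fspec@fs / 2, length.out = nGrid)
  H <- vapply(seq_along(f), function(i) {
    abs(sum(h * exp(-2i * pi * f[i] / fspec@fs * (seq_along(h) - 1))))
  }, numeric(1))
  data.frame(freq = f, db = 20 * log10(pmax(H, 1e-300)))
}

#' Achieved minimum stopband attenuation of the band filter
#'
#' Measures the realised magnitude response of the Kaiser FIR design on a
#' dense frequency grid and returns the minimum attenuation (dB, positive)
#' over the stopband regions, i.e. outside the band edges and their
#' transition widths.
#'
#' @param fspec a [FilterSpec-class]
#' @param nGrid number of grid frequencies between 0 and Nyquist
#' @return minimum stopband attenuation (dB)
#' @export
stopbandAttenuation <- function(fspec, nGrid = 20000) {
  resp <- filterResponseDb(fspec, nGrid)
  df <- fspec@transitionFrac * min(fspec@band@fl, fspec@band@fh)
  stop <- resp$freq <= fspec@band@fl - df | resp$freq >= fspec@band@fh + df
  -max(resp$db[stop])
}

#' Smoothed Hilbert envelope of a recording
#'
#' The envelope is the magnitude of the analytic signal,
#' `E(t) = sqrt(s(t)^2 + H[s](t)^2)` with `H` the Hilbert transform
#' (computed spectrally), then smoothed with a centred moving-average filter
#' of `windowSamples` points.  At the 625 kHz sampling rate of the chamber
#' recordings the default 625-sample window spans exactly 1 ms.
#'
#' @param rec a [Recording-class]
#' @param windowSamples moving-average length in samples (>= 1)
#' @return an [EnvelopeCurve-class]
#' @export
smoothedEnvelope <- function(rec, windowSamples = 625) {
  stopifnot(is(rec, "Recording"))
  n <- length(rec@samples)
  if (n == 0) stop("empty signal")
  if (windowSamples < 1 || windowSamples >= n)
    stop("windowSamples must be >= 1 and shorter than the signal")
  env <- Mod(analyticSignal(rec@samples))
  es <- movingAverage(env, windowSamples)
  new("EnvelopeCurve", values = pmax(es, 0), fs = rec@fs, tauOff = rec@tauOff)
}

## Analytic signal via the spectral method: double positive frequencies,
## zero negative ones.  The FFT length is padded to the next 5-smooth
## number (and truncated afterwards) so awkward prime lengths cannot blow
## up the mixed-radix FFT cost; the padding error is confined to the
## record's final samples.
analyticSignal <- function(x) {
  n0 <- length(x)
  n <- nextSmooth(n0)
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  hmul <- numeric(n)
  if (n %% 2 == 0) {
    hmul[1] <- 1; hmul[n / 2 + 1] <- 1; hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1; hmul[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * hmul, inverse = TRUE)[seq_len(n0)] / n
}

## smallest integer >= n whose prime factors are all in {2, 3, 5}
nextSmooth <- function(n) {
  m <- n
  repeat {
    r <- m
    for (p in c(2, 3, 5)) while (r %% p == 0) r <- r / p
    if (r == 1) return(m)
    m <- m + 1
  }
}

## Centred moving average with edge truncation (partial windows at the ends).
movingAverage <- function(x, w) {
  if (w == 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- floor(w / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (w - half - 1), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Noise-crossing time of a decay envelope
#'
#' Iterative noise-floor/decay-slope intersection in the style of Lundeby's
#' method: the noise level is first estimated from the last 10% of the
#' record, the late decay is regressed on the log-energy curve between the
#' offset level and a 5 dB safety margin above the noise, and the crossing
#' time of the regression line with the noise level is refined over at most
#' 5 iterations.  If the decay never meets the noise floor (effectively
#' noiseless recording) the convention is `tauN` = end of recording.
#'
#' @param env an [EnvelopeCurve-class] (band-limited, smoothed)
#' @param tauOff sound-offset time (s); defaults to the envelope's own
#' @return noise-crossing time `tauN` (s), with `tauOff < tauN <= duration`
#' @export
estimateNoiseTime <- function(env, tauOff = offsetTime(env)) {
  stopifnot(is(env, "EnvelopeCurve"))
  fs <- env@fs
  n <- length(env@values)
  dur <- n / fs
  if (tauOff >= dur) stop("no samples after tauOff")
  i0 <- max(1L, floor(tauOff * fs) + 1L)
  e2 <- env@values[i0:n]^2
  t <- (seq_along(e2) - 1) / fs
  ldb <- 10 * log10(pmax(e2, max(e2) * 1e-30))
  ldb <- ldb - max(ldb[1:max(1, min(10, length(ldb)))])
  ## initial noise estimate: mean energy of last 10% of the record
  tailIdx <- seq(floor(0.9 * length(e2)) + 1, length(e2))
  noiseDb <- 10 * log10(mean(e2[tailIdx]) / max(e2))
  ## a decaying record drops well below its early level by the tail;
  ## a stationary one does not
  earlyIdx <- seq_len(max(1L, floor(0.2 * length(e2))))
  if (10 * log10(mean(e2[earlyIdx]) / mean(e2[tailIdx])) < 5)
    stop("no decay: envelope after the offset is not decaying")
  tauN <- dur
  aFit <- NA_real_
  for (iter in 1:5) {
    ## regress the decay between just under the offset level and 5 dB above
    ## the current noise estimate
    sel <- which(ldb < -1 & ldb > noiseDb + 5 & t < tauN - tauOff)
    if (length(sel) < 10) break
    fit <- stats::lm.fit(cbind(1, t[sel]), ldb[sel])
    a <- fit$coefficients[2]; b <- fit$coefficients[1]
    if (!is.finite(a) || a >= 0)
      stop("no decay: envelope after the offset is not decaying")
    aFit <- a
    cross <- (noiseDb - b) / a
    newTauN <- min(dur, tauOff + cross)
    ## refresh noise estimate from the segment safely after the crossing
    after <- which(t > cross + 0.05 * (dur - tauOff))
    if (length(after) > 20)
      noiseDb <- 10 * log10(mean(e2[after]) / max(e2))
    if (abs(newTauN - tauN) < 1 / fs) { tauN <- newTauN; break }
    tauN <- newTauN
  }
  if (!is.finite(tauN) || tauN <= tauOff)
    stop("no decay: envelope after the offset is not decaying")
  ## noiseless convention: if the record's tail is still decaying at a
  ## material fraction of the fitted decay rate, there is no stationary
  ## floor to cross and tauN is the end of the recording
  if (is.finite(aFit)) {
    tailSel <- t >= 0.85 * max(t)
    if (sum(tailSel) > 10) {
      tailSlope <- stats::lm.fit(cbind(1, t[tailSel]),
                                 ldb[tailSel])$coefficients[2]
      if (is.finite(tailSlope) && tailSlope < 0.25 * aFit) tauN <- dur
    }
  }
  tauN
}

#' Schroeder backward-integrated decay curve
#'
#' Backward integration of the squared smoothed envelope between the sound
#' offset and the noise-crossing time:
#' \deqn{L(t) = 10 \log_{10} \frac{\int_t^{\tau_N} E_s^2\,d\tau}
#'   {\int_{\tau_{off}}^{\tau_N} E_s^2\,d\tau},}
#' which is 0 dB at the offset and non-increasing.  Setting
#' `squared = FALSE` integrates the envelope itself instead of its square;
#' the energy form is the default since reverberation is an energy-decay
#' concept.
#'
#' @param env an [EnvelopeCurve-class]
#' @param tauOff sound-offset time (s)
#' @param tauN noise-crossing time (s), `tauOff < tauN`
#' @param squared integrate the squared envelope (energy, default) or the
#'   envelope itself
#' @param noiseCompensation subtract the stationary noise energy density
#'   (estimated from the record beyond `tauN`) from the integrand before
#'   integrating, removing the upward bias of the curve's tail; ignored
#'   when no samples beyond `tauN` exist
#' @return a [SchroederCurve-class]
#' @export
schroederCurve <- function(env, tauOff = offsetTime(env),
                           tauN = estimateNoiseTime(env, tauOff),
                           squared = TRUE, noiseCompensation = TRUE) {
  stopifnot(is(env, "EnvelopeCurve"))
  if (tauN <= tauOff) stop("tauN must exceed tauOff")
  fs <- env@fs
  i0 <- max(1L, floor(tauOff * fs) + 1L)
  i1 <- min(length(env@values), ceiling(tauN * fs))
  e <- env@values[i0:i1]
  e <- if (squared) e^2 else e
  if (noiseCompensation) {
    after <- env@values[-seq_len(min(length(env@values),
                                     ceiling(tauN * fs) + 1L))]
    if (length(after) > 100) {
      nE <- mean(after^2)
      nE <- if (squared) nE else sqrt(nE)
      e <- pmax(e - nE, 0)
    }
  }
  tot <- sum(e)
  if (tot <= 0) stop("zero energy between tauOff and tauN")
  csum <- rev(cumsum(rev(e)))
  L <- 10 * log10(pmax(csum / tot, 1e-300))
  L <- cummin(L - L[1])    # exact 0 dB start; guard rounding monotonicity
  times <- tauOff + (seq_along(L) - 1) / fs
  new("SchroederCurve", levelDb = L, times = times, tauN = tauN,
      slopeA = NA_real_, interceptB = NA_real_)
}

#' Reverberation time from a Schroeder curve
#'
#' Fits a least-squares line `L'(t) = A t + B` (time measured from the
#' sound offset) to the Schroeder curve over the evaluation range from 0 dB
#' down to `max(L(tauN), -35)` dB, and extrapolates to the -60 dB point:
#' `T60 = -(60 + B)/A`.
#'
#' @param curve a [SchroederCurve-class]
#' @param fitRangeDb lower fitting bound (dB, negative); the effective
#'   bound is the shallower of this and the curve's final level
#' @return list with `t60` (s), `slopeA` (dB/s), `interceptB` (dB) and the
#'   input `curve` updated with the fitted line
#' @export
estimateT60 <- function(curve, fitRangeDb = -35) {
  stopifnot(is(curve, "SchroederCurve"))
  if (length(curve@levelDb) < 10) stop("need at least 10 curve samples")
  lower <- max(min(curve@levelDb), fitRangeDb)
  sel <- curve@levelDb >= lower
  if (sum(sel) < 10) sel <- seq_len(length(curve@levelDb))
  t <- curve@times[sel] - curve@times[1]
  fit <- stats::lm.fit(cbind(1, t), curve@levelDb[sel])
  B <- unname(fit$coefficients[1]); A <- unname(fit$coefficients[2])
  if (!is.finite(A) || A >= 0) stop("no decay: fitted slope is not negative")
  t60 <- -(60 + B) / A
  if (t60 <= 0) stop("no decay: extrapolated T60 not positive")
  curve@slopeA <- A; curve@interceptB <- B
  list(t60 = t60, slopeA = A, interceptB = B, curve = curve)
}

#' Reverberation time of one recording in one band
#'
#' Runs the full single-position chain: bandpass filter, smoothed envelope,
#' noise-crossing time, Schroeder integration, regression.
#'
#' @param rec a [Recording-class]
#' @param band a [Band-class]
#' @param windowSamples envelope smoothing length (samples); default is
#'   the 1 ms window (625 samples at the 625 kHz chamber rate)
#' @param fitRangeDb lower regression bound passed to [estimateT60()]
#' @param ... passed to [FilterSpec()]
#' @return list as from [estimateT60()], plus `tauN`
#' @export
recordingT60 <- function(rec, band, windowSamples = round(sampleRate(rec) / 1000),
                         fitRangeDb = -35, ...) {
  fspec <- FilterSpec(band, sampleRate(rec), ...)
  filt <- bandpassFilter(rec, fspec)
  env <- smoothedEnvelope(filt, windowSamples)
  tauN <- estimateNoiseTime(env)
  sc <- schroederCurve(env, tauN = tauN)
  res <- estimateT60(sc, fitRangeDb)
  res$tauN <- tauN
  res
}

#' Spatially averaged reverberation time over microphone positions
#'
#' Applies the full estimation chain to each recording and returns the
#' arithmetic mean of the per-position T60 values.  Positions whose
#' estimation fails are excluded with a warning; if all fail, an error is
#' raised.
#'
#' @param recordings list of [Recording-class] objects (microphone positions)
#' @param band a [Band-class]
#' @param ... passed to [recordingT60()]
#' @return a [ReverbMeasurement-class]
#' @export
bandT60 <- function(recordings, band, ...) {
  stopifnot(length(recordings) >= 1)
  vals <- vapply(recordings, function(r) {
    tryCatch(recordingT60(r, band, ...)$t60,
             error = function(e) {
               warning("position '", r@positionId, "' excluded: ",
                       conditionMessage(e), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("reverberation-time estimation failed at every position")
  ReverbMeasurement(band, mean(vals), length(vals))
}
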