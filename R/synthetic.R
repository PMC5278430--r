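## Synthetic-data generation: band-limited exponential energy decays with a
## stationary noise floor (chamber recordings), paired empty/with-wings
## recording sets with known absorption truth, two-class wing photographs
## with known pixel truth, and balanced repeated-measures absorption tables.

#' Specification of one synthetic decay recording
#'
#' @slot band excitation [Band-class]
#' @slot t60True target reverberation time (s)
#' @slot steadyDur steady-state duration before the sound offset (s)
#' @slot recordDur total recording duration (s)
#' @slot noiseFloorDb stationary noise level relative to the steady state
#'   (dB, negative)
#' @slot seed RNG seed
#' @export
setClass("DecaySpec",
         representation(band = "Band", t60True = "numeric",
                        steadyDur = "numeric", recordDur = "numeric",
                        noiseFloorDb = "numeric", seed = "integer"))

setValidity("DecaySpec", function(object) {
  if (object@t60True <= 0) return("t60True must be positive")
  if (object@steadyDur <= 0 || object@recordDur <= object@steadyDur)
    return("need 0 < steadyDur < recordDur")
  if (object@noiseFloorDb >= 0) return("noiseFloorDb must be negative")
  TRUE
})

#' @rdname DecaySpec-class
#' @param band a [Band-class]
#' @param t60True target reverberation time (s)
#' @param steadyDur steady-state duration (s)
#' @param recordDur total duration (s)
#' @param noiseFloorDb noise floor relative to steady state (dB)
#' @param seed RNG seed
#' @export
DecaySpec <- function(band, t60True, steadyDur = 0.05,
                      recordDur = steadyDur + 6 * t60True,
                      noiseFloorDb = -60, seed = 1L)
  new("DecaySpec", band = band, t60True = as.numeric(t60True),
      steadyDur = as.numeric(steadyDur), recordDur = as.numeric(recordDur),
      noiseFloorDb = as.numeric(noiseFloorDb), seed = as.integer(seed))

#' Generate a band-limited steady-state decay recording
#'
#' Emulates a chamber measurement: band-limited Gaussian noise whose
#' ensemble amplitude is constant up to the sound offset (`tauOff =
#' steadyDur`) and decays as `exp(-6.9078 (t - tauOff) / t60)`
#' afterwards, so the energy envelope decays at exactly `60/t60` dB/s.  An
#' independent stationary band-limited noise floor at `noiseFloorDb`
#' relative to the steady-state energy is added.  Output is bit-identical
#' for a fixed spec seed.
#'
#' @param spec a [DecaySpec-class]
#' @param fs sampling frequency (Hz); must exceed twice the band's upper edge
#' @return a [Recording-class] with `tauOff = steadyDur`
#' @export
genDecayRecording <- function(spec, fs = 625e3) {
  stopifnot(is(spec, "DecaySpec"))
  if (fs <= 2 * spec@band@fh) stop("fs must exceed twice the band's upper edge")
  n <- round(spec@recordDur * fs)
  withSeed(spec@seed, {
    x <- stats::rnorm(n)
    v <- stats::rnorm(n)
  })
  fspec <- FilterSpec(spec@band, fs)
  h <- kaiserDesign(fspec)
  bl <- function(z) {
    y <- signal::fftfilt(h, c(z, numeric(length(h))))
    d <- (length(h) - 1) / 2
    y[(d + 1):(d + length(z))]
  }
  x <- bl(x); v <- bl(v)
  x <- x / stats::sd(x); v <- v / stats::sd(v)
  t <- (seq_len(n) - 1) / fs
  k <- 3 * log(10) / spec@t60True              # energy decay 60/t60 dB/s
  amp <- ifelse(t < spec@steadyDur, 1, exp(-k * (t - spec@steadyDur)))
  sig <- x * amp + v * 10^(spec@noiseFloorDb / 20)
  Recording(sig, fs, tauOff = spec@steadyDur,
            positionId = sprintf("seed%d", spec@seed))
}

#' Generate paired empty/with-wings chamber recording sets with known truth
#'
#' Inverts the chamber equations: the empty-chamber reverberation time `T0`
#' is the one that yields `alpha0True`, and the with-wings time `T1` the one
#' that yields `alphawTrue` on top of that `T0`.  Per-position reverberation
#' times are jittered uniformly by `jitter` (default +-2%) to emulate
#' residual non-diffuseness of the chamber field, and each position is
#' rendered with [genDecayRecording()].  The jitter is a fixed spatial
#' pattern of the chamber: position `i` carries the same factor in the
#' empty and with-wings runs (the microphone occupies the same locations
#' both times), so shared positions cancel in the before/after comparison.
#'
#' @param chamber a [ChamberSpec-class]
#' @param air an [AirProperties-class]
#' @param band a [Band-class]
#' @param alpha0True true empty-chamber absorption factor (> 0)
#' @param alphawTrue true wing absorption factor
#' @param Sw wing planform area (m^2)
#' @param nPosEmpty,nPosWings number of microphone positions
#' @param fs sampling frequency (Hz)
#' @param seed RNG seed
#' @param noiseFloorDb recording noise floor (dB re steady state)
#' @param jitter per-position relative T jitter half-width
#' @param steadyDur steady-state duration per recording (s)
#' @param recordDurFactor total duration as `steadyDur + factor * T` (s)
#' @return list with `empty` and `wings` (lists of [Recording-class]) and
#'   `truth` (list with `T0`, `T1`, `alpha0True`, `alphawTrue`)
#' @export
genPairedChamberRecordings <- function(chamber, air, band, alpha0True,
                                       alphawTrue, Sw,
                                       nPosEmpty = 27, nPosWings = 4,
                                       fs = 625e3, seed = 1L,
                                       noiseFloorDb = -60, jitter = 0.02,
                                       steadyDur = 0.02,
                                       recordDurFactor = 2.2) {
  stopifnot(alpha0True > 0)
  T0 <- invertEmptyChamberAlpha(chamber, band, alpha0True, air)
  T1 <- invertWingAlpha(chamber, band, T0, alphawTrue, Sw, air)
  nPos <- max(nPosEmpty, nPosWings)
  withSeed(seed * 1000L, jit <- stats::runif(nPos, 1 - jitter, 1 + jitter))
  gen <- function(Tnom, nPos, seedBase) {
    lapply(seq_len(nPos), function(i) {
      spec <- DecaySpec(band, Tnom * jit[i], steadyDur = steadyDur,
                        recordDur = steadyDur + recordDurFactor * Tnom,
                        noiseFloorDb = noiseFloorDb,
                        seed = seedBase + i)
      r <- genDecayRecording(spec, fs)
      r@positionId <- sprintf("pos%02d", i)
      r
    })
  }
  list(empty = gen(T0, nPosEmpty, seed * 1000L),
       wings = gen(T1, nPosWings, seed * 1000L + 500L),
       truth = list(T0 = T0, T1 = T1,
                    alpha0True = alpha0True, alphawTrue = alphawTrue))
}

#' Render a synthetic wing-set photograph with known pixel truth
#'
#' Dark elliptical wing silhouettes on a white background of known area,
#' placed without overlap, with optional additive Gaussian pixel noise.
#' Intensities are on [0, 1]; wings are rendered at 0.2 and background at
#' 1.0 before noise.
#'
#' @param nWings number of wing silhouettes
#' @param canvasPx image size as `c(rows, cols)`
#' @param Sb background reference area (m^2)
#' @param noiseSd Gaussian noise standard deviation as a fraction of the
#'   wing/background contrast
#' @param seed RNG seed
#' @param maxTries placement retries before giving up
#' @return list with `image` (numeric matrix), `trueCount` (exact rendered
#'   wing pixel count) and `Sb`
#' @export
genWingImage <- function(nWings, canvasPx = c(600, 600), Sb = 0.04,
                         noiseSd = 0, seed = 1L, maxTries = 200L) {
  nr <- canvasPx[1]; nc <- canvasPx[2]
  img <- matrix(1, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  rows <- row(img); cols <- col(img)
  withSeed(seed, {
    placed <- 0
    tries <- 0
    while (placed < nWings) {
      tries <- tries + 1
      if (tries > maxTries)
        stop("could not place ", nWings, " non-overlapping wings")
      a <- stats::runif(1, 0.08, 0.16) * nc     # semi-axes in pixels
      b <- stats::runif(1, 0.05, 0.10) * nr
      cx <- stats::runif(1, a + 2, nc - a - 2)
      cy <- stats::runif(1, b + 2, nr - b - 2)
      th <- stats::runif(1, 0, pi)
      dx <- cols - cx; dy <- rows - cy
      u <- dx * cos(th) + dy * sin(th)
      v <- -dx * sin(th) + dy * cos(th)
      ell <- (u / a)^2 + (v / b)^2 <= 1
      if (any(ell & mask)) next
      mask <- mask | ell
      placed <- placed + 1
    }
    img[mask] <- 0.2
    if (noiseSd > 0) img <- img + stats::rnorm(nr * nc, 0, noiseSd * 0.8)
  })
  list(image = img, trueCount = sum(mask), Sb = Sb)
}

#' Generate a balanced repeated-measures absorption table
#'
#' Long-format dataset with the measurement design used throughout the
#' package: preparations (each belonging to a group) crossed with wing sets
#' (subjects) and third-octave bands.  Each record is
#' `alpha = mean(preparation, band) + subject effect + residual`, with
#' normal subject effects (`sdSubject`) and residuals (`sd`).
#'
#' @param groupBandMeans data.frame with columns `preparation`, `group` and
#'   one mean per band (`fc_hz`, `mean`), i.e. long format with columns
#'   `preparation, group, fc_hz, mean`
#' @param sd residual standard deviation (> 0)
#' @param nSets wing sets (subjects) per preparation
#' @param sdSubject subject random-effect standard deviation
#' @param seed RNG seed
#' @return data.frame with columns `preparation, group, set_id, fc_hz, alpha`
#' @export
genRMDataset <- function(groupBandMeans, sd = 0.05, nSets = 6,
                         sdSubject = 0.03, seed = 1L) {
  stopifnot(is.data.frame(groupBandMeans),
            all(c("preparation", "group", "fc_hz", "mean") %in%
                  names(groupBandMeans)))
  if (sd <= 0) stop("sd must be positive")
  preps <- unique(groupBandMeans$preparation)
  bands <- sort(unique(groupBandMeans$fc_hz))
  out <- vector("list", length(preps) * nSets)
  withSeed(seed, {
    idx <- 0
    for (p in preps) {
      gm <- groupBandMeans[groupBandMeans$preparation == p, ]
      gm <- gm[order(gm$fc_hz), ]
      grp <- gm$group[1]
      for (s in seq_len(nSets)) {
        idx <- idx + 1
        subj <- stats::rnorm(1, 0, sdSubject)
        out[[idx]] <- data.frame(
          preparation = p, group = grp,
          set_id = sprintf("%s_set%d", p, s),
          fc_hz = bands,
          alpha = gm$mean + subj + stats::rnorm(length(bands), 0, sd))
      }
    }
  })
  do.call(rbind, out)
}

#' Default preparation design of the study
#'
#' Nine preparations — three chalcosiine species plus male and female of
#' three saturniid species — with smooth per-band mean absorption spectra
#' peaking near 20-25 kHz: chalcosiines near 0.4, saturniids near 0.6 with
#' females above males.
#'
#' @param bands list of [Band-class] objects (default 8 bands, 20-100 kHz)
#' @return data.frame usable as `groupBandMeans` in [genRMDataset()]
#' @export
defaultPreparationMeans <- function(bands = thirdOctaveBands()) {
  fc <- vapply(bands, bandCentre, numeric(1))
  shape <- function(peak) peak * exp(-((log(fc / 22e3))^2) / 0.9)
  preps <- data.frame(
    preparation = c("A_a_analis", "C_burmanus", "E_pulchera",
                    "A_io_f", "A_mittrei_f", "S_c_ricini_f",
                    "A_io_m", "A_mittrei_m", "S_c_ricini_m"),
    group = rep(c("chalcosiine", "female-saturniid", "male-saturniid"),
                each = 3),
    peak = c(0.38, 0.40, 0.42, 0.58, 0.62, 0.64, 0.52, 0.50, 0.48))
  do.call(rbind, lapply(seq_len(nrow(preps)), function(i)
    data.frame(preparation = preps$preparation[i], group = preps$group[i],
               fc_hz = fc, mean = shape(preps$peak[i]))))
}

## Run expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
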