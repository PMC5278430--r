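test_that("bandpass filter preserves in-band tones and kills out-of-band ones", {
  b <- Band(20000); fs <- 625e3
  fspec <- FilterSpec(b, fs)
  n <- 50000
  t <- (0:(n - 1)) / fs
  rms <- function(x) sqrt(mean(x[10000:40000]^2))
  tone <- function(f) Recording(cos(2 * pi * f * t), fs)
  inb <- bandpassFilter(tone(20000), fspec)
  expect_equal(rms(samples(inb)), rms(samples(tone(20000))), tolerance = 0.01)
  out <- bandpassFilter(tone(0.5 * bandEdges(b)["fl"]), fspec)
  atten <- 20 * log10(rms(samples(tone(1000))) / rms(samples(out)))
  expect_gte(atten, 80)
  expect_error(FilterSpec(Band(300000), fs), "Nyquist")
  expect_error(FilterSpec(b, fs, stopAttenDb = 60), "80")
})

test_that("realised filter response matches the design across the grid", {
  ## the measured transfer magnitude never exceeds unity gain by more than
  ## the passband ripple, is flat in-band, and is >= 80 dB down in stopband
  fspec <- FilterSpec(Band(20000), 625e3)
  resp <- echowing:::filterResponseDb(fspec, 4000)
  pass <- resp$freq >= bandEdges(fspec@band)["fl"] &
    resp$freq <= bandEdges(fspec@band)["fh"]
  expect_lt(max(abs(resp$db[pass])), 1)
  expect_gte(stopbandAttenuation(fspec, 4000), 80)
})

test_that("group delay compensation preserves the sound-offset time", {
  b <- fixtureBand(); fs <- 250e3
  rec <- quickRecording(0.02, noiseFloorDb = -80, seed = 9)
  filt <- bandpassFilter(rec, FilterSpec(b, fs))
  expect_equal(offsetTime(filt), offsetTime(rec))
  ## energy decay must start at tau_off, not taps/2 samples later
  env <- smoothedEnvelope(filt, 250)
  fs <- sampleRate(env)
  i <- function(tau) round(tau * fs)
  lateDb <- 20 * log10(env@values[i(offsetTime(rec) + 0.008)] /
                         env@values[i(offsetTime(rec) - 0.005)])
  expect_lt(lateDb, -15)
})

test_that("smoothed envelope recovers tone amplitude and the 1 ms window", {
  fs <- 625e3
  t <- (0:99999) / fs
  rec <- Recording(3.7 * cos(2 * pi * 40e3 * t), fs)
  env <- smoothedEnvelope(rec, 625)
  mid <- env@values[20000:80000]
  expect_equal(mean(mid), 3.7, tolerance = 0.01)
  expect_equal(625 / fs, 1e-3)     # the default window spans exactly 1 ms
  expect_error(smoothedEnvelope(rec, 0), "windowSamples")
  ## exponentially decaying tone: log-envelope slope matches decay constant
  ## (fit kept above the ~-85 dB leakage floor of the spectral Hilbert)
  k <- 150
  rec2 <- Recording(exp(-k * t) * cos(2 * pi * 40e3 * t), fs)
  env2 <- smoothedEnvelope(rec2, 313)
  sel <- 10000:35000
  fit <- lm(log(env2@values[sel]) ~ t[sel])
  expect_equal(unname(coef(fit)[2]), -k, tolerance = 0.02)
})

test_that("noise-crossing time finds the constructed intersection", {
  fs <- 250e3
  ## envelope: flat 20 ms, then exponential decay crossing a -50 dB floor
  t60 <- 0.025
  k <- 3 * log(10) / t60
  tauOff <- 0.02
  t <- (0:(0.12 * fs)) / fs
  floorAmp <- 10^(-50 / 20)
  e <- pmax(ifelse(t < tauOff, 1, exp(-k * (t - tauOff))), floorAmp)
  env <- new("EnvelopeCurve", values = e, fs = fs, tauOff = tauOff)
  tStar <- tauOff + (50 / 60) * t60            # where decay meets floor
  tauN <- estimateNoiseTime(env)
  expect_lt(abs(tauN - tStar) / (tStar - tauOff), 0.2)
  ## noiseless decay: convention tauN = end of recording
  e2 <- ifelse(t < tauOff, 1, exp(-k * (t - tauOff)))
  env2 <- new("EnvelopeCurve", values = e2, fs = fs, tauOff = tauOff)
  expect_equal(estimateNoiseTime(env2), length(e2) / fs, tolerance = 1e-6)
  ## stationary noise only: no decay
  set.seed(1)
  env3 <- new("EnvelopeCurve", values = abs(rnorm(10000)) + 0.5, fs = fs,
              tauOff = 0.002)
  expect_error(estimateNoiseTime(env3), "no decay")
})

test_that("Schroeder curve starts at 0 dB and is monotone on random inputs", {
  for (s in 1:20) {
    rec <- quickRecording(t60 = runif(1, 0.01, 0.05),
                          noiseFloorDb = runif(1, -70, -45), seed = 1000 + s)
    env <- smoothedEnvelope(bandpassFilter(rec, FilterSpec(fixtureBand(),
                                                           sampleRate(rec))),
                            250)
    sc <- schroederCurve(env)
    expect_identical(sc@levelDb[1], 0)
    expect_true(all(diff(sc@levelDb) <= 0))
  }
})

test_that("Schroeder slope of a pure exponential matches the closed form", {
  fs <- 250e3
  k <- 100
  t <- (0:(0.2 * fs)) / fs
  env <- new("EnvelopeCurve", values = exp(-k * t), fs = fs, tauOff = 0)
  sc <- schroederCurve(env, tauOff = 0, tauN = 0.2, noiseCompensation = FALSE)
  ## L(t) for E = exp(-kt): slope -20 k / ln(10) dB/s
  sel <- sc@levelDb > -30
  fit <- lm(sc@levelDb[sel] ~ sc@times[sel])
  expect_equal(unname(coef(fit)[2]), -20 * k / log(10), tolerance = 0.005)
  ## halving tauN leaves the fitted slope essentially unchanged
  sc2 <- schroederCurve(env, tauOff = 0, tauN = 0.1, noiseCompensation = FALSE)
  sel2 <- sc2@levelDb > -30
  fit2 <- lm(sc2@levelDb[sel2] ~ sc2@times[sel2])
  expect_equal(unname(coef(fit2)[2]), unname(coef(fit)[2]), tolerance = 0.01)
  expect_error(schroederCurve(env, tauOff = 0.3, tauN = 0.2), "tauN")
})

test_that("T60 regression implements the -60 dB extrapolation", {
  ## exact line at -1000 dB/s: T60 = 60 ms
  fs <- 1e4
  times <- (0:999) / fs
  sc <- new("SchroederCurve", levelDb = -1000 * times, times = times,
            tauN = 0.1, slopeA = NA_real_, interceptB = NA_real_)
  res <- estimateT60(sc)
  expect_equal(res$t60, 0.060, tolerance = 1e-9)
  expect_equal(res$slopeA, -1000, tolerance = 1e-6)
  ## dilating the time axis doubles the estimate
  sc2 <- new("SchroederCurve", levelDb = -1000 * times, times = 2 * times,
             tauN = 0.2, slopeA = NA_real_, interceptB = NA_real_)
  expect_equal(estimateT60(sc2)$t60, 0.120, tolerance = 1e-9)
  ## a flat curve has no decay
  scFlat <- new("SchroederCurve", levelDb = rep(0, 100), times = times[1:100],
                tauN = 0.1, slopeA = NA_real_, interceptB = NA_real_)
  expect_error(estimateT60(scFlat), "no decay")
})

test_that("band T60 averages positions arithmetically and drops failures", {
  b <- fixtureBand()
  recs <- list(quickRecording(0.020, seed = 21), quickRecording(0.030, seed = 22))
  m <- bandT60(recs, b)
  single <- vapply(recs, function(r) recordingT60(r, b)$t60, numeric(1))
  expect_equal(reverbTime(m), mean(single), tolerance = 1e-12)
  expect_equal(m@nPositions, 2L)
  ## identical recordings: mean equals the single estimate
  m2 <- bandT60(list(recs[[1]], recs[[1]], recs[[1]]), b)
  expect_equal(reverbTime(m2), single[1], tolerance = 1e-12)
  ## a flat position is excluded with a warning, not fatal
  flat <- Recording(rnorm(30000), 250e3, tauOff = 0.02)
  expect_warning(m3 <- bandT60(c(recs, list(flat)), b), "excluded")
  expect_equal(m3@nPositions, 2L)
  expect_error(suppressWarnings(bandT60(list(flat), b)), "every position")
})

test_that("T60 recovery is accurate through the full single-band chain", {
  errs <- vapply(1:8, function(s) {
    rec <- quickRecording(0.030, noiseFloorDb = -60, seed = 300 + s)
    recordingT60(rec, fixtureBand())$t60 / 0.030 - 1
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.05)
})
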