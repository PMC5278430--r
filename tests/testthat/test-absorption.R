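test_that("preferred third-octave bands cover 20-100 kHz with 8 centres", {
  bands <- thirdOctaveBands(20e3, 100e3)
  expect_length(bands, 8)
  expect_equal(vapply(bands, bandCentre, numeric(1)),
               c(20000, 25000, 31500, 40000, 50000, 63000, 80000, 100000))
  for (b in bands)
    expect_equal(unname(bandEdges(b)["fh"] / bandEdges(b)["fl"]), 2^(1/3),
                 tolerance = 1e-9)
  one <- thirdOctaveBands(20e3, 20e3)
  expect_length(one, 1)
  expect_equal(bandCentre(one[[1]]), 20000)
  expect_error(thirdOctaveBands(5e4, 2e4), "fcLo")
})

test_that("band air attenuation follows the classical f^2 law", {
  air <- fixtureAir()
  b1 <- Band(20000); b2 <- Band(40000)
  m1 <- airAttenuationBand(b1, air)$m1
  m2 <- airAttenuationBand(b2, air)$m1
  expect_equal(m2 / m1, 4, tolerance = 1e-9)   # doubled edges, x4 coefficient
  expect_gt(m1, 0)
  ## increases with centre frequency across the default band set
  ms <- vapply(thirdOctaveBands(), function(b) airAttenuationBand(b, air)$m1,
               numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("band-averaged attenuation equals numerical quadrature", {
  air <- fixtureAir()
  b <- Band(20000)
  const <- 4 * pi^2 / (air@rho * air@c^3) *
    ((4 / 3) * air@mu + (air@gamma - 1) * air@kTh / air@Cp)
  edges <- bandEdges(b)
  quad <- stats::integrate(function(f) const * f^2, edges["fl"], edges["fh"],
                           rel.tol = 1e-12)$value / diff(edges)
  expect_equal(airAttenuationBand(b, air)$m1, unname(quad), tolerance = 1e-10)
  ## degenerate band limit reduces to the single-frequency coefficient
  degenerate <- b
  degenerate@fl <- 20000; degenerate@fh <- 20000
  expect_equal(airAttenuationBand(degenerate, air)$m1,
               const * 20000^2, tolerance = 1e-12)
})

test_that("thermal dissipation vanishes as gamma approaches 1", {
  airV <- AirProperties(gamma = 1 + 1e-12)
  airFull <- fixtureAir()
  b <- Band(20000)
  viscousOnly <- airAttenuationBand(b, airV)$m1
  full <- airAttenuationBand(b, airFull)$m1
  expect_lt(viscousOnly, full)
  ## the viscous term alone survives
  expected <- 4 * pi^2 / (airV@rho * airV@c^3) * (4 / 3) * airV@mu *
    (bandEdges(b)["fh"]^3 - bandEdges(b)["fl"]^3) / (3 * diff(bandEdges(b)))
  expect_equal(viscousOnly, unname(expected), tolerance = 1e-9)
})

test_that("empty-chamber absorption matches direct arithmetic", {
  ch <- fixtureChamber(); air <- fixtureAir(); b <- Band(20000)
  T0 <- ReverbMeasurement(b, 0.025, 27L)
  m1 <- airAttenuationBand(b, air)$m1
  oracle <- 24 * log(10) * ch@V / (air@c * ch@S * 0.025) - 4 * m1 * ch@V / ch@S
  expect_equal(emptyChamberAlpha(ch, b, T0, air), oracle, tolerance = 1e-12)
  ## Sabine-term scaling: the m1-free part halves when T0 doubles
  a1 <- emptyChamberAlpha(ch, b, 0.02, air) + 4 * m1 * ch@V / ch@S
  a2 <- emptyChamberAlpha(ch, b, 0.04, air) + 4 * m1 * ch@V / ch@S
  expect_equal(a1 / a2, 2, tolerance = 1e-12)
  expect_error(emptyChamberAlpha(ch, b, -1, air), "positive")
})

test_that("wing absorption matches direct arithmetic and its limits", {
  ch <- fixtureChamber(); air <- fixtureAir(); b <- Band(20000)
  geom <- WingSetGeometry(Sw = 0.005, Sb = 0.04)
  oracle <- 24 * log(10) * ch@V / (air@c * 0.005) * (1 / 0.020 - 1 / 0.025)
  expect_equal(wingAlpha(ch, b, 0.025, 0.020, geom, air), oracle,
               tolerance = 1e-12)
  expect_identical(wingAlpha(ch, b, 0.025, 0.025, geom, air), 0)
  expect_error(wingAlpha(ch, b, 0.025, 0.020, WingSetGeometry(0, 0.04), air),
               "Sw")
})

test_that("absorption factors decrease in the respective reverberation time", {
  ch <- fixtureChamber(); air <- fixtureAir(); b <- Band(50000)
  geom <- WingSetGeometry(Sw = 0.01, Sb = 0.04)
  T0grid <- seq(0.005, 0.06, length.out = 12)
  a0 <- vapply(T0grid, function(T0) emptyChamberAlpha(ch, b, T0, air),
               numeric(1))
  expect_true(all(diff(a0) < 0))
  T1grid <- seq(0.004, 0.02, length.out = 12)
  aw <- vapply(T1grid, function(T1) wingAlpha(ch, b, 0.021, T1, geom, air),
               numeric(1))
  expect_true(all(diff(aw) < 0))
})

test_that("alpha is recovered from synthetic recordings (single-band check)", {
  ch <- fixtureChamber(); air <- fixtureAir(); b <- fixtureBand()
  sim <- genPairedChamberRecordings(ch, air, b, 0.15, 0.5, Sw = 0.02,
                                    nPosEmpty = 12, nPosWings = 12,
                                    fs = 250e3, seed = 7)
  T0 <- bandT60(sim$empty, b, fitRangeDb = -45)
  T1 <- bandT60(sim$wings, b, fitRangeDb = -45)
  a0 <- emptyChamberAlpha(ch, b, T0, air)
  aw <- wingAlpha(ch, b, T0, T1, WingSetGeometry(0.02, 0.04), air)
  expect_equal(a0, 0.15, tolerance = 0.05)
  expect_equal(aw, 0.5, tolerance = 0.1)
})
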