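## Shared fixtures: a small Perspex-like chamber (20 cm cube scale), default
## air, and the wide analysis band used for estimator validation (widest
## bandwidth -> most precise single-position reverberation estimates).

fixtureChamber <- function() ChamberSpec(V = 0.008, S = 0.28)
fixtureAir <- function() AirProperties()
fixtureBand <- function() Band(80000)

## One synthetic decay recording at the validation sampling rate.
quickRecording <- function(t60 = 0.03, noiseFloorDb = -60, seed = 1L,
                           band = fixtureBand(), fs = 250e3,
                           steadyDur = 0.02, durFactor = 2.2) {
  spec <- DecaySpec(band, t60, steadyDur = steadyDur,
                    recordDur = steadyDur + durFactor * t60,
                    noiseFloorDb = noiseFloorDb, seed = seed)
  genDecayRecording(spec, fs)
}

## Null repeated-measures dataset: identical means everywhere.
nullRMData <- function(seed, sd = 0.05, sdSubject = 0.03) {
  means <- defaultPreparationMeans()
  means$mean <- 0.4
  genRMDataset(means, sd = sd, nSets = 6, sdSubject = sdSubject, seed = seed)
}
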