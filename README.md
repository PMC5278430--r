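# echowing

Ultrasonic absorption of moth wings, measured the reverberation-chamber
way, and what it buys a moth when a bat comes hunting.

Moth wing scales form a porous layer that absorbs part of an incident
echolocation cry; a more absorbent wing returns a weaker echo and the moth
is detected at a shorter range. `echowing` implements the full desk side of
such a study for anyone working on acoustic anti-predator adaptations or
small-chamber ultrasonic absorption measurements:

* **Reverberation time** from steady-state decay recordings: third-octave
  Kaiser FIR bandpass (≥ 80 dB stopband), Hilbert envelope with 1 ms
  moving-average smoothing, iterative noise-crossing-time estimation,
  Schroeder backward integration of the energy envelope, and linear
  regression extrapolated to −60 dB
  (T<sub>60</sub> = −(60 + B)/A for the fitted line At + B).
* **Absorption factors** from paired reverberation times, Sabine-style:
  α₀ = 55.26 V/(c S T₀) − 4 m₁ V/S for the empty chamber and
  α_w = 55.26 V/(c S_w) (1/T₁ − 1/T₀) for the introduced wings, with m₁
  the band-averaged classical thermoviscous air absorption coefficient.
* **Wing planform area** from photographs: bilateral smoothing, two-class
  k-means++ binarisation, S_w = (N_w/N) · S_b.
* **Repeated-measures statistics** on absorption tables: between-subjects
  ANOVA on marginal means, Mauchly sphericity test, Greenhouse–Geisser
  corrected within-subject ANOVA, Tukey–Kramer pairwise comparisons overall
  and per band.
* **Detection-distance comparison** of two targets differing only in wing
  absorption, via the sonar equation solved in closed form with the Lambert
  W function: 40 log₁₀ r₁ + 2λr₁ − 10 log₁₀(1−α₁) =
  40 log₁₀ r₂ + 2λr₂ − 10 log₁₀(1−α₂).
* **Synthetic data** for all of the above — band-limited exponential decays
  with a stationary noise floor, wing silhouettes with exact pixel truth,
  and balanced 9-preparation × 6-set × 8-band absorption tables — so the
  whole pipeline is testable without hardware or specimens.

## Worked example

How much closer can a bat approach before detecting a female whose wings
absorb 60% of the incident energy at 25 kHz, against a male reference at
35% absorption detected at 5 m?

```r
library(echowing)

lam <- atmosphericAttenuation(25e3, tempC = 20, rh = 70)
lam
#> [1] 0.6180928

res <- detectionDistanceFemale(
  SonarScenario(r2 = 5, lam = lam, alpha1 = 0.60, alpha2 = 0.35))
res$r1
#> [1] 4.567568
res$pctDiff
#> [1] 8.648641
```

The female is detected at 4.57 m — an 8.6% shorter detection distance from
that one absorption difference at one frequency. `percentDifferenceSpectrum()`
evaluates this per band and per reference distance for whole absorption
spectra.

The measurement chain itself round-trips on synthetic recordings:

```r
b <- Band(80000)
rec <- genDecayRecording(
  DecaySpec(b, t60True = 0.030, steadyDur = 0.02, recordDur = 0.09,
            noiseFloorDb = -60, seed = 1), fs = 250e3)
est <- recordingT60(rec, b)
sprintf("T60 = %.4f s (truth 0.0300), tauN = %.4f s, slope = %.0f dB/s",
        est$t60, est$tauN, est$slopeA)
#> [1] "T60 = 0.0304 s (truth 0.0300), tauN = 0.0491 s, slope = -1991 dB/s"
```

`runPipeline()` chains every stage (simulate → T60 → absorption → area →
statistics → detection) into per-stage CSVs plus a JSON run report, driven
by a YAML chamber configuration and a single seed.

See the vignette `vignettes/chamber-method.Rmd` for the model, parameter
choices, the synthetic generator's assumptions, and known limitations.

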