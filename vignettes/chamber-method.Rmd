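---
title: "Measuring ultrasonic wing absorption with a small reverberation chamber"
author: "echowing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ultrasonic wing absorption with a small reverberation chamber}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echowing)
```

## The measurement problem

Echolocating bats detect moths by the echo their wings return.  Wing scales
form a porous layer that absorbs part of the incident ultrasound, so a
strongly absorbing wing returns a weaker echo and the moth is detected at a
shorter range.  `echowing` implements the complete desk side of a
reverberation-chamber study of this effect: estimating reverberation times
from steady-state decay recordings, converting them to random-incidence
absorption factors, measuring wing planform area from photographs, comparing
absorption spectra across species and sexes with a repeated-measures model,
and translating an absorption difference into a detection-distance
difference through the sonar equation.

Because no chamber recordings or specimens ship with the package, a
synthetic generator produces every input with known ground truth.  All
validation is round-trip: generate with known parameters, estimate, compare.

## Reverberation-time estimation

A measurement drives one third-octave band (centres 20–100 kHz, edge ratio
$2^{1/3}$) to a steady state and records the decay after the excitation
stops at $\tau_{off}$, at a sampling rate of 625 kHz.  The estimation chain
is:

1. **Bandpass filtering.**  A linear-phase FIR filter designed with a
   Kaiser window passes $[f_l, f_h]$ and attenuates everything else by at
   least 80 dB.  The empirical Kaiser order formula locates its nominal
   transition width at the ripple band rather than at the point where the
   full attenuation is reached, so the design uses half the stated
   transition width plus a 2 dB margin; the realised response is then
   verified on a dense grid (`stopbandAttenuation()`).  The filter's
   constant group delay is compensated by shifting the output, so
   $\tau_{off}$ stays aligned.
2. **Envelope.**  $E(t) = \sqrt{s^2 + \hat s^2}$ with $\hat s$ the Hilbert
   transform (computed spectrally), smoothed by a centred moving average of
   1 ms (625 samples at 625 kHz).
3. **Noise-crossing time.**  $\tau_N$, the time where the regressed late
   decay meets the stationary noise floor, found by the iterative
   floor/slope-intersection scheme: initial floor from the last 10% of the
   record, decay regressed between the offset level and a 5 dB safety
   margin above the floor, at most 5 refinement iterations.  A noiseless
   record yields $\tau_N$ = end of record by convention; a record that
   never drops 5 dB below its early level is rejected as having no decay.
4. **Schroeder integration.**  $L(t) = 10 \log_{10} \int_t^{\tau_N}
   E_s^2\,d\tau \,/\, \int_{\tau_{off}}^{\tau_N} E_s^2\,d\tau$, the
   backward-integrated energy decay, which starts at 0 dB and is monotone
   non-increasing.  The integrand is the *squared* smoothed envelope by
   default — reverberation is an energy-decay concept — with the plain
   envelope selectable (`squared = FALSE`).  The stationary noise energy
   estimated beyond $\tau_N$ is subtracted from the integrand first
   (`noiseCompensation`), which removes the upward bias of the curve's
   tail.
5. **Regression.**  A least-squares line $L'(t) = At + B$ is fitted from
   0 dB down to $\max(L(\tau_N), -35)$ dB and extrapolated:
   $T_{60} = -(60 + B)/A$.  The −35 dB default keeps clear of the noise
   floor in the worst supported case (a −50 dB floor); with quieter floors
   a deeper bound (e.g. −45 dB) uses more of the curve and roughly halves
   the estimator's spread, and the validation tests do so where the floor
   permits.

Per-band reverberation times are averaged arithmetically over microphone
positions (`bandT60()`), matching spatial averaging of measured
reverberation times rather than of their reciprocals.

A single interrupted-noise decay is a random realisation: the relative
spread of the fitted slope scales like $1/\sqrt{B\,T_{60}}$ with $B$ the
band's width.  At the 80 kHz band ($B \approx 18.5$ kHz) and
$T_{60} = 38$ ms a single position carries about 1% spread; at the 20 kHz
band it is nearer 4%.  Spatial averaging divides this by $\sqrt{n}$.

## Absorption factors

With $V$ the chamber volume, $S$ its surface area, $c$ the speed of sound
and $m_1$ the air volume absorption coefficient, the empty-chamber
absorption factor is the Sabine-type expression

$$\alpha_0 = \frac{55.26\,V}{c\,S\,T_0} - \frac{4 m_1 V}{S},$$

and the wing absorption factor follows from the before/after comparison

$$\alpha_w = \frac{55.26\,V}{c\,S_w}\left(\frac 1{T_1} - \frac 1{T_0}\right),$$

with $S_w$ the planform area of the introduced wings.  The air-attenuation
terms cancel in the difference because both measurements are taken under
the same air conditions; $T_1 = T_0$ gives exactly $\alpha_w = 0$.

$m_1$ is the classical thermoviscous coefficient
$m(f) = \frac{4\pi^2 f^2}{\rho c^3}\big(\tfrac43\mu + (\gamma-1)k/C_p\big)$
averaged over the band, $\frac{f_h^3 - f_l^3}{3(f_h - f_l)}$ replacing
$f^2$.  Defaults for the air constants are standard values at 20 °C
(overridable in the YAML config); at 100 kHz the correction reaches a few
percent of $\alpha_0$ and grows as $f^2$.

Absorption factors are deliberately **not clamped** to $[0, 1]$:
measurement noise can push individual values outside the physical range,
and clamping would bias spatial and per-set averages.  Out-of-range values
are kept raw and flagged with a warning.

The band set defaults to the 8 preferred third-octave centres 20, 25, 31.5,
40, 50, 63, 80, 100 kHz.  `thirdOctaveBands()` returns whatever preferred
centres fall in the requested range, so wider variants are available by
widening the range.

## The synthetic generator

`genDecayRecording()` emulates one chamber measurement: band-limited
Gaussian noise with constant ensemble amplitude before $\tau_{off}$ and
amplitude law $\exp(-6.9078\,(t-\tau_{off})/T_{60})$ afterwards — an energy
decay of exactly $60/T_{60}$ dB/s — plus an independent stationary
band-limited noise floor at a stated level below the steady state.  The
stimulus statistics after the offset are the generator's own choice;
filtered white noise is the standard idealisation of a diffuse-field decay.

`genPairedChamberRecordings()` inverts the two absorption equations to find
the $T_0$ and $T_1$ implied by target values $\alpha_0$ and $\alpha_w$, and
renders per-position recordings.  Position-to-position variability of the
reverberation time (residual non-diffuseness) is a uniform ±2% jitter.
The jitter is treated as a *fixed spatial pattern of the chamber*: position
$i$ carries the same factor in the empty and with-wings runs, as a
microphone revisiting the same locations would experience, so shared
positions cancel in the before/after difference.

What the generator does **not** emulate: room modes and their frequency
structure, non-exponential (multi-slope) decays, transducer and microphone
responses, temperature drift between the paired runs.  Passing round-trip
tests therefore validates the estimation chain, not the physical apparatus.

`genWingImage()` renders non-overlapping dark elliptical silhouettes
(intensity 0.2) on a white background (1.0) with optional Gaussian pixel
noise, returning the exact rendered pixel count.  Ellipse unions stand in
for real wing outlines because only the pixel-count truth matters for the
area formula.

`genRMDataset()` produces the study's balanced design — 9 preparations
(3 chalcosiine species, male and female of 3 saturniid species) × 6 wing
sets × 8 bands = 432 records, 48 per preparation, 144 per group — as
cell mean + normal subject effect + normal residual.
`defaultPreparationMeans()` provides smooth spectra peaking near 20–25 kHz,
chalcosiines near 0.4 and saturniids near 0.6 with females above males,
the magnitudes this kind of study reports.

## Wing area from photographs

`segmentWings()` smooths the image with an edge-preserving bilateral filter
(spatial σ 3 px, range σ 10% of the intensity range — chosen as mild
defaults that denoise flat regions without moving the wing/background
edge) and clusters pixel intensities with 2-class k-means, seeded by the
k-means++ rule with 5 restarts, keeping the best within-cluster inertia.
The darker cluster is labelled wing (`wingsBright` inverts).  The area is
the pixel fraction times the known background area:
$S_w = (N_w/N)\,S_b$.  Validation uses analytically known ellipse areas
(&lt;2% error at 1000×1000 px with noise) and exactness in the noiseless
two-level case.

## Detection-distance comparison

The sonar equation in dB form, $D = H - 2K + M + e$ with one-way
transmission loss $K = 20\log_{10} r + \lambda r$ and target strength
$M = 10\log_{10}(I_r/I_i)$, is written for two targets that differ only in
wing absorption ($I_r/I_i \propto 1-\alpha$).  Subtracting cancels $D$,
$H$, $e$ and the shared geometry, leaving

$$40\log_{10} r_1 + 2\lambda r_1 - 10\log_{10}(1-\alpha_1)
 = 40\log_{10} r_2 + 2\lambda r_2 - 10\log_{10}(1-\alpha_2),$$

solved in closed form by the principal real branch of the Lambert $W$
function: with $a = \lambda\ln 10/20$ and $b$ the right-hand side times
$\ln 10/40$, $r_1 = W(a e^b)/a$ (and $r_1 = e^b$ at $\lambda = 0$, the
quarter-power law $r_1 = r_2\,[(1-\alpha_1)/(1-\alpha_2)]^{1/4}$).  The
returned root is verified against the defining equality (residual below
$10^{-9}$ dB) and, in tests, against bisection.

$\lambda(f)$ comes from the standard humid-air absorption model
(oxygen and nitrogen relaxation plus the classical term) at a stated
temperature and humidity, defaulting to 20 °C and 70% RH; a tabulated value
can be supplied per band via `lamOverride`.

`percentDifferenceSpectrum()` evaluates the comparison per band and per
reference distance (defaults 1, 5, 10 m, the range over which bats
typically detect moths) and reports $100\,(r_2 - r_1)/r_2$.

## Statistics

`fitRM()` arranges the long table into a subjects × bands matrix (subjects
are wing sets) and computes cell means, per-subject marginal means, and the
pooled within-level covariance.  On top of it:

* `betweenAnova()` — classical one-way ANOVA on the marginal means;
  df (8, 45) for the 9-preparation design, (2, 51) for the 3-group design.
* `withinAnova()` — balanced split-plot F tests for the frequency main
  effect and the interaction; df (7, 315) and (56, 315), or (7, 357) and
  (14, 357) by group.  Under the Greenhouse–Geisser correction the
  epsilon multiplies both dfs and the p-value uses the corrected,
  non-integer dfs directly in the F distribution.
* `sphericity()` — Mauchly's W with the standard chi-square approximation
  (including the second-order term) and the Greenhouse–Geisser epsilon from
  the eigenvalues of the contrast-projected covariance, bounded in
  $[1/(k-1), 1]$.
* `tukeyKramer()` — studentized-range pairwise comparisons on marginal
  means (overall) or on one band's values.  Per-band tests use each band's
  own one-way error term with no additional correction across bands; the
  three-tier markers (0.05/0.01/0.001) match the reporting convention of
  this literature.

Both within-subject tests are exact under sphericity; the GG-corrected
p-values are slightly conservative there, so the null-calibration tests
(type-I error in [0.03, 0.07] at nominal 0.05) exercise the uncorrected
tests under a compound-symmetric null, where uniform p-values are the
correct expectation.

## Validation configuration and problem sizes

Round-trip accuracy of $\alpha_w$ is limited by error amplification in the
difference $1/T_1 - 1/T_0$: the relative error of $\alpha_w$ is roughly the
relative error of the averaged reverberation times divided by the relative
gap between them.  The package's validation configuration therefore uses
the 80 kHz band (widest bandwidth, hence the most precise single-position
estimates), a long empty-chamber time ($\alpha_0 = 0.1$), wings covering
half the chamber floor ($S_w = 0.02$ m² of $S_b = 0.04$ m²,
$V = 0.008$ m³, $S = 0.28$ m²), 250 kHz sampling, 40 shared microphone
positions per condition, a −45 dB regression bound, and medians over 20
seeds.  Under a field-typical protocol (4 microphone positions for $T_1$,
small wing sets), the same amplification makes a 5% recovery of small $\alpha_w$
statistically unattainable no matter how exact the estimator — a property
of the difference method itself, worth keeping in mind when reading
measured absorption spectra.

Numerical conventions: all dB are $10\log_{10}$ of energy-like ratios;
times in seconds, frequencies in Hz, SI throughout.  FFT lengths are padded
to 5-smooth numbers.  Degenerate inputs (constant images, flat envelopes,
zero wing area, bands at or above Nyquist) are rejected with explicit
errors rather than propagated.

## Limitations

* Steady-state decays only; impulse-response methods (MLS, sweeps) are out
  of scope.
* No ISO-354-strict absorption measurement — hence "absorption factor",
  not "coefficient".
* The difference method's error amplification at small $\alpha_w$ and small
  specimen area, as quantified above.
* Atmospheric attenuation is formula-based; measured tables can be
  substituted per band where available.
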