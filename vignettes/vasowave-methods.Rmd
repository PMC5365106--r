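---
title: "Methods: speckle-variance vasomotion analysis in vasowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle-variance vasomotion analysis in vasowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasowave)
```

vasowave detects rhythmic flow oscillations — vasomotion (~0.1–0.3 Hz in
the rat retina) and Mayer-band activity (~0.3–0.7 Hz in rats) — in laser
speckle contrast recordings. This vignette explains the model behind each
stage, the parameters that matter, the numerical choices, and what the
synthetic test bed does and does not establish about real data.

## 1. Speckle variance

Coherent light scattered by tissue forms a speckle pattern; motion of red
blood cells blurs it within the camera exposure, reducing local intensity
contrast. The package works with the speckle-variance statistic

$$SV = \bar I^2 / \sigma^2,$$

computed over a $5\times5$ sliding window (25 pixels, step 1 px), where
$\bar I$ and $\sigma$ are the window mean and standard deviation. For fully
developed static speckle the contrast $\sigma/\bar I$ is 1, so $SV = 1$;
flow raises $SV$. $SV$ is a *relative* flow index: no exposure-time
decorrelation model is fitted, and absolute perfusion is out of scope.

Numerical conventions, chosen once and tested:

* **Sample variance (divisor $n-1$).** Which divisor a given instrument
  uses is rarely stated; the unbiased sample variance makes the
  calibration claims below well defined. At $n = 25$ the difference is 4%.
* **Borders and degenerate windows.** Pixels whose full window does not
  fit inside the frame, and windows with zero variance (constant,
  saturated or synthetic-static regions), are marked *invalid* rather than
  padded or set to $\infty$. Invalid pixels are excluded from every
  downstream average; this avoids biasing vessel-edge SV with partial
  windows.
* **Scale invariance.** $SV(c\,I) = SV(I)$ for any $c>0$; the test suite
  asserts it, and every downstream statistic inherits it.

Temporal downsampling block-averages 25 consecutive frames, taking 50 fps
raw recordings to 2 fps SV data — ample for sub-Hz rhythms (Nyquist
1 Hz) and a 25-fold data reduction. The order of operations is *SV first,
then temporal averaging of SV maps*; averaging intensities before SV is
possible with the same functions but is not the default, because temporal
intensity averaging changes the speckle statistics that $SV$ is defined
on. A trailing partial block is discarded rather than averaged short.

### Gamma intensity model and small-sample calibration

The synthetic stack generator draws each pixel of each frame independently
from a Gamma distribution whose *shape* parameter carries the pixel's
instantaneous target SV (for Gamma$(k,\theta)$, mean$^2$/variance $= k$
exactly). This reproduces the first two moments that $SV$ measures without
simulating coherent optics.

The moment identity holds for *population* moments; the windowed
estimator $\bar x^2/s^2$ at $n=25$ is biased upward by roughly 10–17%
(the dominant term is $\mathrm{E}[1/s^2] > 1/\sigma^2$, inflated further
by the Gamma's skewness at small shape). The generator therefore, by
default, *calibrates* the shape: a deterministic internal Monte-Carlo
sweep maps shape to the expected windowed estimate, and the map is
inverted so that downstream $5\times5$ SV maps are unbiased for the
requested target. The acceptance suite verifies recovery within 5% for
targets 1, 2, 4 and 8 (tens of thousands of windows per target).
`calibrate = FALSE` restores the raw moment parameterization
(shape $=$ target).

## 2. Vessel extraction

Given a mean SV frame and an ROI polygon (coordinates: 0-based, x right,
y down, pixel centers at integers — fixed so ROI JSON files are portable):

1. **Mask**: in-ROI pixels with mean SV strictly above the
   `threshold_quantile` (default 0.5) of in-ROI values; largest
   8-connected component; $3\times3$ morphological closing.
2. **Centerline**: Zhang–Suen thinning to a 1-px skeleton, then the
   longest geodesic path by double-sweep BFS. A skeleton whose longest
   path covers less than half its pixels is rejected as "strongly
   branched" with advice to tighten the ROI — the extractor is built for a
   single vessel per ROI, not for network graphs.
3. **Series**: at each centerline point the local tangent is taken from a
   ±2-point central difference; SV is sampled at unit steps along the
   perpendicular, by nearest-pixel lookup, walking outward until the mask
   is left; each scan line is averaged, then scan-line means are averaged
   along the centerline. Nearest-pixel lookup (no interpolation) is
   deliberate: SV maps are already spatially smoothed by the $5\times5$
   window. Invalid pixels are skipped; a frame with no valid sample
   becomes `NA` and is bridged by linear interpolation before the wavelet
   transform.

Motion-artifact handling is limited to mask-restricted averaging and
missing-point flagging — appropriate for paralyzed-animal or synthetic
recordings. Image registration would be the extension point for awake
data.

## 3. Morlet wavelet spectra

The analytic Morlet mother wavelet
$\psi(u) = \pi^{-1/4} e^{i\omega_0 u} e^{-u^2/2}$ with $\omega_0 = 6$
(the standard choice respecting admissibility, for which scale converts to
frequency as $f = \omega_0/(2\pi a)$ to within 0.3%) is applied as

$$W(a,b) = \frac{1}{a} \int x(t)\, \psi^*\!\Big(\frac{t-b}{a}\Big)\, dt ,$$

evaluated by FFT convolution with the kernel truncated at $|u| \le 8$
(amplitude $e^{-32}$; the suite verifies agreement with a brute-force
direct sum to $10^{-6}$ relative). Two normalizations are exposed: the
default $1/a$ (under which white-noise energy rises $\propto f$) and an
$L^2$-preserving $1/\sqrt a$ variant. Peak *ratios at a common frequency*
are insensitive to the choice; detection counts are not, so the
normalization is recorded with every spectrum.

* **Frequency grid**: log-spaced, 12 voices/octave, 0.05 Hz to
  $\min(9.6, \mathrm{fps}/2.5)$ Hz — resolves both analysis bands on 2 Hz
  SV data and the ~6.4 Hz cardiac line on 50 Hz validation data, with
  margin below Nyquist.
* **Edges**: zero padding plus a cone of influence at one e-folding time
  $\sqrt 2\, a$ from either edge; COI cells are excluded from window
  averages. A series shorter than $2\sqrt2\,a_{\max}$ is rejected with
  the minimum usable length in the message.
* **Protocol windows**: energy is averaged per frequency over a 10-min
  window starting 10 min into each protocol period (control 35 min,
  drug 1 30 min, drug 2 30 min). The control window mirrors the drug
  windows (minutes 10–20) since the control period is itself an infusion
  (saline).

### Spectral smoothing at the transform's resolution

A 10-min average at 2 Hz contains only $N_\mathrm{eff} \sim 25$–80
independent $|W|^2$ samples per frequency in the vasomotion band (the
wavelet's integral time scale is $\sqrt{2\pi}\,a$), so the averaged
spectrum carries $1/\sqrt{N_\mathrm{eff}} \approx 10\text{–}20\%$
stochastic ripple. Against a 10% detection threshold (next section), raw
ripple produces spurious "peaks". Averaged spectra are therefore smoothed
before peak analysis with a Gaussian kernel in log-frequency whose sd
equals the Morlet kernel's own relative frequency resolution,
$\mathrm{bw} = 1/\omega_0$ in $\ln f$ (≈ 2.9 grid steps at 12
voices/octave). This bandwidth is parameter-free: it removes only
sub-resolution structure that cannot represent a resolvable oscillation,
and leaves any transform-resolvable peak in place. The smoother uses
reflection padding in log-frequency, because a one-sidedly truncated
kernel on a sloped spectrum drags edge maxima toward the grid boundary.
Smoothing is switchable (`smooth_bw = 0`) and the applied bandwidth is
recorded on the spectrum.

Two practical consequences, both visible in the test suite:

* Peaks within about one smoothing bandwidth of the *grid* edge are
  biased; grids are built with headroom above the highest band of
  interest (the tone-recovery property test uses a full octave).
* For smoothed spectra the "interior of the band" used by the peak finder
  widens from one grid step to the kernel sd: maxima parked within a
  kernel width of a band edge by the smoothing-slope interaction are not
  accepted as in-band peaks. Raw spectra keep the one-step margin.

## 4. Peak-prominence statistics

Within band 1 (0.1–0.3 Hz) and band 2 (0.3–0.7 Hz):

* **Peak**: the strict interior local maximum with the largest
  *prominence* $E(f_\mathrm{peak}) - E_b$; ties break toward the lower
  frequency; a band with no interior maximum legitimately has *no* peak.
  Band-edge maxima are never peaks — a rising spectral slope must not
  masquerade as an oscillation.
* **Background $E_b$**: median of in-band energies excluding grid points
  within ±20% (in frequency) of the peak; whole-band median (with a
  warning) if the exclusion empties the band. The band-wide median is a
  deliberate choice over a local baseline fit: referencing the peak to the
  whole band suppresses small maxima riding low on a sloped noise floor,
  which a local baseline would happily certify as 10% above themselves.
* **Energy ratio** $E = E_r(f_r)/E_c(f_r)$: response energy at the
  response peak frequency over *control energy at that same frequency* —
  defined whenever the response has a peak, control peak or not.
* **Prominence ratio** $P = P_r/P_c$ with $P_x = E_x(f_x) - E_{xb}$, each
  spectrum at its own peak. The response side requires a genuine interior
  peak (that is the detection); the control side is only a reference
  level, so when the control spectrum is featureless in the band — the
  typical case for a quiescent vessel — $P_c$ falls back to the
  prominence of the in-band energy maximum above background. Without this
  fallback, drug-*initiated* activity in a previously silent vessel would
  have an undefined $P$, and induced-vasomotion counts would
  systematically miss exactly the vessels they are meant to count.
* **Flags and counts** (threshold 1.1 = "at least 10% above", a config
  value): spontaneous ($E_c(f_c)/E_{cb} > 1.1$, the $m$ counts),
  increased ($P > 1.1$, the $n$ counts), above background
  ($E_r(f_r)/E_{rb} > 1.1$), induced (above background *and* not
  spontaneous). A value exactly at the threshold is not counted. Missing
  spectra yield missing flags, never `FALSE`.
* **Summaries**: per-animal rows plus a Total row with $N$, $m_1$, $m_2$,
  $n_1$, $n_2$, and mean ± SD (sample SD, $n-1$) of $E$ and $f$ over the
  increased vessels per band. Frequencies of induced vasomotion are
  compared between the two drug periods by a paired two-sided t-test on
  per-vessel differences; all-zero differences report $p = 1$ with a
  note, fewer than two complete pairs reports the test as undefined.

Detection at a 10% threshold on 10-minute spectra is intentionally
liberal, and even after resolution-matched smoothing a noise-only vessel
retains a small per-vessel probability of a false spontaneous detection;
over large cohorts the expected false-positive count is of order one
vessel. This is a property of the threshold criterion itself, not of the
implementation; raising the threshold parameter trades sensitivity for
specificity monotonically (a property test asserts the monotonicity).

## 5. The synthetic test bed

`generate_cohort()` builds full-protocol cohorts at 2 Hz: baseline SV 4,
oscillation relative amplitude 0.2, additive white Gaussian noise with sd
defaulting to amplitude RMS / 5 (SNR 5), spontaneous oscillators uniform
in 0.15–0.20 Hz (band 1) or 0.40–0.50 Hz (band 2) active throughout,
induced oscillators at fixed 0.17 Hz / 0.45 Hz active only in their drug
period with 60 s linear ramps (hard switching would splatter energy
across the spectrum). `generate_pressure_signal()` provides a 50 Hz
validation signal with pulse 6.4 Hz, ventilation 1.0 Hz and Mayer 0.5 Hz
components over 1/f noise, mirroring the cross-modality check that the
speckle spectra reproduce systemic rhythms seen in arterial pressure.

Everything is reproducible: one integer seed pins the RNG (kind pinned
too), and the manifest records every component, so detection output can
be scored against ground truth exactly.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: coherent speckle optics (per-pixel
independent Gamma draws have no spatial speckle grain or exposure-time
decorrelation), eye or animal motion, drug pharmacokinetics beyond an
amplitude envelope, vessel diameter changes (flow modulation is imposed
directly on SV), non-Gaussian or nonstationary measurement noise, and
spectral leakage between neighbouring vessels. Synthetic oscillation
amplitudes are free parameters of the test bed, recorded in the manifest;
they are not claims about physiological effect sizes.

## 6. Problem sizes and tolerances

The test suite runs in about a minute on one core: oracle equivalences on
8 × 8 frames and 64-sample series (SV to $10^{-12}$ relative, CWT to
$10^{-6}$), Gamma-calibration on ~10⁴ windows per target (5% tolerance),
tone recovery over 20 seeds (one grid step), an 81-vessel cohort with 8
ground-truth spontaneous oscillators recovered exactly at the tested
seed, 20-vessel induced cohorts recovering 0.17/0.45–0.46 Hz within one
grid step, and 1000 null simulations bounding the paired t-test's type-I
error within [0.03, 0.07] at $\alpha = 0.05$. These sizes were chosen as
the smallest that make each statistical tolerance meaningful.

## 7. Known limitations

* The exact Morlet variant and scale–frequency conversion used by any
  given commercial toolbox differ in detail; $\omega_0$, the
  normalization and the grid are config-exposed, and results should be
  reported with that configuration attached.
* The centerline extractor targets single, mildly curved vessels; strong
  branching inside an ROI is rejected rather than resolved.
* Cohort detection counts near threshold are stochastic by nature; with
  the default conditions the spontaneous-count false-positive expectation
  is below one vessel per 73 quiet vessels, but individual seeds can add
  one or two.
* No multiple-testing correction is applied across vessels, and no
  red-noise significance test is performed on spectra — detection is by
  the fixed prominence threshold alone.
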