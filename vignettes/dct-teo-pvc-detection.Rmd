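---
title: "Detecting premature ventricular contractions from DCT-Teager energy envelopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting premature ventricular contractions from DCT-Teager energy envelopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvcdct)
```

## The problem and the statistic

A premature ventricular contraction (PVC) is an ectopic beat that starts in
the ventricular muscle instead of the sinoatrial node. Because the impulse
does not travel the fast conduction system, the QRS complex is wide and the
P wave is absent. A wide, smooth deflection concentrates its spectral energy
at low frequencies, so in the DCT domain a PVC packs its energy into fewer
leading coefficients than a narrow-QRS normal beat. This package turns that
observation into a per-beat classifier.

For a beat window $x[n]$, $n = 0 \dots N-1$, centred on the R peak, the
orthonormal DCT-II is

$$X_c[k] = c_k \sqrt{2/N} \sum_{n=0}^{N-1} x[n]
  \cos\!\left(\frac{\pi}{N}\left(n+\tfrac12\right)k\right),
  \qquad c_0 = 1/\sqrt2,\; c_k = 1 \text{ otherwise.}$$

The envelope of the beat's system function is estimated by applying the
Teager–Kaiser energy operator along the coefficient index,

$$E[k] = X_c[k]^2 - X_c[k-1]\,X_c[k+1],$$

which for a sampled sinusoid $A\cos(\Omega n + \phi)$ equals
$A^2\sin^2\Omega$ at every interior sample: it measures the energy of the
oscillator generating the signal, growing with frequency as well as
amplitude, where the conventional sum-of-squares energy sees amplitude only
(`demo_teo()` reproduces this two-tone contrast). The energy packing
efficiency (EPE) curve accumulates the squared envelope over the first
$M = \min(N, 150)$ coefficients,

$$\varepsilon_i = \frac{\sum_{j \le i} E_j^2}{\sum_{j < M} E_j^2},$$

and the **decay rate** is the smallest 0-based index with
$\varepsilon_i \ge 0.9$. Wide-QRS beats reach 90% within a handful of
coefficients; narrow-QRS normal beats need a few dozen. A beat is called a
PVC when its decay rate is at or below a threshold.

The classical baseline replaces the Teager step by cepstral smoothing:
`dct_cepstrum_envelope()` low-pass lifters `log(|X_c| + delta)` (ideal
rectangular lifter, default cutoff $L = 15$ quefrency bins, floor
$\delta = 10^{-12}\max|X_c|$) and exponentiates back. The beat is modelled
as an action potential convolved with an excitation, so the log magnitude
splits into a smooth system part plus fine structure; the lifter keeps the
smooth part. We formulate the cepstral step directly on the DCT magnitude
sequence — the liftered log-magnitude is the envelope *as a function of the
coefficient index* — because that is the quantity whose decay the
classifier measures; a flat coefficient sequence then maps to a flat
envelope, as it should. Note the ideal lifter leaves Gibbs ripple at the
$\sim N/(2L-1)$ index scale, so envelope decay is meaningful at block
resolution, not sample-by-sample.

## Parameters and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| window `W` | 256 | samples | ≈0.71 s at 360 Hz: covers one beat, power of two, ≥150 coefficients for the EPE truncation |
| `fs` | 360 | Hz | the MIT-BIH Arrhythmia Database rate |
| truncation `M` | 150 | coefficients | beat coefficients decay to zero well before index 150; truncating the EPE denominator to the same range guarantees the curve ends at 1 |
| EPE level | 0.9 | fraction | the energy fraction defining the decay rate |
| EPE power | 2 | — | the curve accumulates squared envelope entries; `power = 1` is available because "90% of the energy" of a quantity that is already an energy is ambiguous |
| lifter `L` | 15 | quefrency bins | standard homomorphic-smoothing order for windows of this length |
| threshold (TEO) | 13 | coefficients | see below |
| threshold (cepstrum) | 19 | coefficients | see below |
| jitter CV | 0.05 | fraction | per-beat morphological variability of the generator |

**Threshold calibration.** The decay-rate scale depends on the window
length, sampling rate and beat morphology, so a portable constant does not
exist; published decay-rate bands for real records at one (unstated) window
length do not transfer to another. The package therefore ships a
calibration rule rather than a magic number: `calibrate_threshold()` runs
the clean, jitter-free reference morphologies through the pipeline and
places the threshold at the floored midpoint of the PVC and normal decay
rates. At the package defaults this gives 13 for the Teager method (clean
decay rates 7 and 20) and 19 for the cepstrum baseline (10 and 28); a test
pins the shipped constants to the rule. Users working at other settings
should recalibrate — the rule, not the constants, is the design.

**Boundary and indexing conventions.** The Teager operator zeroes its two
boundary samples (no neighbour exists; zeros add nothing to EPE sums).
Negative Teager values are passed through unrectified — the EPE squares
them. Decay rates are 0-based indices; `compare_methods()` also reports
them as counts (`+1`) because published tables may use either convention.
Windows are half-open around the R sample: `W/2` samples before, `W/2`
from the R sample on.

## The synthetic generator

`generate_beat()` builds each morphology as a sum of Gaussian waves
(amplitude mV, centre s, width = σ in s) on the window time grid:

* **normal** — P(0.15, −0.20, 0.025), Q(−0.10, −0.025, 0.010),
  R(1.00, 0, 0.012), S(−0.20, 0.025, 0.010), T(0.30, 0.20, 0.060);
* **pvc** — R(1.30, 0, 0.035), S(−0.40, 0.06, 0.030), discordant
  T(−0.35, 0.28, 0.080), no P wave; QRS full width at half maximum ≈2.9×
  the normal preset;
* **paced** — a 4 ms pacing spike followed by a wide evoked complex;
* **lbbb/rbbb** — two partially overlapping R lobes with the second/first
  lobe widened (the split-QRS shape of bundle-branch block). The lobe
  values are this package's choice; only the narrow-vs-wide contrast is
  load-bearing.

Per-beat jitter multiplies every amplitude and width by independent
lognormal factors with unit mean and CV 5%, keeping both positive. All
randomness flows from one seed; `generate_beatset()` shuffles with the same
stream.

What the generator does *not* emulate: sharp multiphasic QRS notching,
baseline variation within the clean beat, rhythm context (RR intervals),
electrode artifacts, and the full morphological diversity of real records.
Consequently the synthetic decay-rate bands (TEO: PVC 5–8, normal 16–22 at
5% jitter) sit below the published real-record bands, and perfect
separation on synthetic data shows the statistic works as designed — not
that real-data performance is perfect.

## Noise models and the measured operating envelope

Three corruptions are applied to the time-domain beat before the DCT:
white Gaussian noise at a target SNR (reference: mean power over the full
beat window — the package fixes this definition because SNR is meaningless
without one), sinusoidal mains interference (50/60 Hz), and low-frequency
baseline wander (0.1 Hz, near-monotone within one window). Relative
interference amplitudes are resolved against the *set-median* peak-to-peak
range: mains pickup and baseline drift belong to the recording, so every
beat receives the same added waveform rather than one scaled to its own
QRS height.

The test suite measures where detection holds (all figures computed by the
suite on the default 100+100 synthetic set):

* **Gaussian noise**: Se and +P stay at 100% down to 0 dB. At −5 dB the
  robustness test fails: noise power is $10^{0.5}\times$ signal power
  spread uniformly over all retained coefficients, and once the flat noise
  floor carries a sizeable share of the truncated squared-envelope energy
  the cumulative curve cannot reach 0.9 inside the beat's compact band.
  This is a physical limit of the statistic at `W = 256`, not an
  implementation artifact; longer windows dilute the per-window mean power
  and push the breakdown lower.
* **Mains interference**: the 50 Hz component lands at coefficient
  $k \approx 2NF/f_s \approx 71$, far above the decay region, so detection
  is unaffected until the interference bin dominates — a knife edge near
  0.25 mV (at 0.2 mV amplitude the suite measures Se, +P ≥ 95%). Because
  the EPE raises coefficients to the fourth power the transition is sharp:
  at the set-median-scaled default (≈0.28 mV) a quarter of PVC beats jump
  to decay rate 71 and fail.
* **Baseline wander**: a quarter-range amplitude (0.25 × p2p) leaves
  Se = +P ≥ 95%. At the half-range demo amplitude the near-DC component
  dominates the low-index envelope of *every* beat, the normal decay rates
  collapse onto the PVC band, and no threshold separates — the
  corresponding robustness assertion fails by design rather than being
  weakened. High-pass detrending before the DCT would remove this failure
  mode but is deliberately out of scope: the statistic is evaluated as
  defined.

```{r robustness, eval = FALSE}
set <- generate_beatset(100, 100, seed = 0)
compare_methods(set, noise_specs = list(
  noise_spec("pli", amplitude = 0.2),
  noise_spec("baseline", amplitude_rel = 0.25),
  noise_spec("gaussian", snr_db = 0, seed = 1)
))
```

## Numerical choices

* The DCT is computed through a cached orthonormal transform matrix;
  forward and inverse are exact adjoints, Parseval holds to rounding, and
  the forward transform is pinned to a brute-force double-sum oracle at
  $10^{-12}$ in the tests.
* The conventional energy is the time-domain sum of squares, equal to the
  total squared DFT magnitude by Parseval; a spectral definition without a
  stated summation convention is not computable.
* `epe_curve()` uses `|E|^power`, so the curve is a valid nondecreasing
  cumulative fraction for either power setting; an all-zero truncated
  envelope is a degenerate-input error, not a silent zero.
* The two-tone demonstration uses a 160-sample window (0.4 s at 400 Hz),
  an integer number of cycles for both tones, so their sum-of-squares
  energies agree exactly; the mean Teager energy over the window includes
  the two zeroed boundary samples, hence equals the closed form times
  158/160. With peak amplitude 4 this yields 7.90 and 1.51 energy units
  for 50 Hz and 20 Hz; an amplitude-2 reading would give 2.0 and 0.38.
  The low tone is 20 Hz: only that frequency is consistent with the
  energy pair above and with the ~5.24 energy ratio
  $\sin^2(\pi/4)/\sin^2(\pi/10)$.
* Kaiser's small-angle statement is implemented and tested in both
  readings: the frequency estimate $\sin\Omega \approx \Omega$ errs by
  <11% up to $\Omega = \pi/4$ (i.e. $f < f_s/8$), while the *energy*
  approximation $A^2\Omega^2$ errs by up to 23.4% on the same range. A
  claim of 11% energy accuracy up to $f_s/4$ holds in neither reading.

## Problem sizes

The default study set is 100 normal + 100 PVC beats at 5% jitter
(window 256, 360 Hz); tests use 10–100 beats per class. These sizes give
fully separated decay-rate distributions with margins of several
coefficients, so larger sets would not change any conclusion the suite
draws.

## Known limitations

* The decay-rate scale — and therefore any fixed threshold — is tied to
  the window length and sampling rate; use `calibrate_threshold()` after
  changing either.
* Paced, LBBB and RBBB beats have wide QRS complexes and PVC-like decay
  rates by construction; the binary threshold rule will call them PVC.
  Distinguishing them needs the envelope shape, not just its decay rate.
* No QRS detector is included; R locations come from annotations or the
  generator. No resampling, multi-lead fusion, or rhythm features.
* The WFDB importer reads signal format 212 (the MIT-BIH format) only,
  channel selection without multi-frequency layouts, and never downloads.
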