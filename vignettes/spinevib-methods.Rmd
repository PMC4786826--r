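---
title: "Vibration-based structural health monitoring of the lumbar spine: models and methods"
author: "spinevib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibration-based structural health monitoring of the lumbar spine: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinevib)
```

## The problem

Structural health monitoring (SHM) assesses a structure's mechanical
integrity from its response to applied vibration. Applied non-invasively to
the lumbar spine, the protocol is: a shaker delivers a pulse train of ten
one-second pulses of randomized frequencies spanning 1–2000 Hz to the
spinous process of T12 under a small (5 N) static preload; five skin-mounted
uniaxial accelerometers over the spinous processes of L1–L5 record the
response at 5000 Hz; three pulse trains are collected per subject. Each
sensor's response is summarized by its frequency response function (FRF)
relative to the measured input force, and the FRF is reduced to three scalar
outcomes: the frequency at peak amplitude (PEAK), the area under the curve
(AUC), and the root mean square (RMS). In a monozygotic twin design,
within-pair differences of these outcomes are tested against zero —
separately for pairs whose spines are structurally concordant on MRI and for
pairs in which one twin carries a localized structural alteration
(discordant pairs).

`spinevib` implements this full chain as tested, reusable code: a synthetic
cohort generator standing in for the in-vivo recordings (which are not
publicly available), spectral estimation, outcome extraction with
coherence-based sensor quality control, and the twin-paired statistics.

## The simulated spine

The instrumented spine is idealized as a lumped-parameter chain: six point
masses (T12, L1–L5) joined by spring–damper links, with T12 additionally
restrained to ground by a spring–damper standing in for the shaker preload
and the thorax. The shaker force drives the T12 mass; the measured signal at
each lumbar node is the node's acceleration multiplied by a distance-dependent
soft-tissue attenuation gain, plus additive white Gaussian sensor noise.
This is deliberately the simplest model that exhibits the features the
analysis must cope with: in-band resonances that move when local stiffness
changes, distance-dependent signal loss, and a noise floor that degrades
coherence at distal sensors.

Default parameters (all tunable through `spine_model()`):

| parameter | default | unit | rationale |
|---|---|---|---|
| node masses | 0.25 each | kg | effective segmental mass of vertebra plus moving tissue |
| link stiffnesses | $8\times10^6 \cdot 1.5^{\,0..4}$ | N/m | posteroanterior stiffness, increasing caudally |
| link dampings | 320 each | N·s/m | heavy tissue damping; see below |
| ground restraint | $4\times10^6$, 160 | N/m, N·s/m | preload/thorax boundary at T12 |
| sensor attenuation | 1, 0.8, 0.6, 0.4, 0.02 | – | soft-tissue loss growing with distance |
| noise RMS | 0.25 | m/s² | accelerometer + skin-motion noise floor |

Two of these choices are load-bearing and were made once, on physical
grounds, when the generator was designed:

* **Caudally increasing stiffness and heavy damping.** With a uniform chain
  and light damping, several resonances have near-equal FRF peak amplitude
  at some sensors, and the *global* argmax (PEAK) then jumps between modes
  under small parameter perturbations — a measurement artifact, not a
  structural signal. The graded, heavily damped chain gives each sensor one
  clearly dominant resonance, so PEAK responds smoothly to parameter changes
  the way the in-vivo FRFs (which show a single dominant peak) do.
* **Noise and attenuation jointly calibrated to the observed coherence
  decline.** The defaults give per-sensor in-band mean coherence of about
  0.88, 0.86, 0.82, 0.72 at L1–L4 and 0.15 at L5 for a default subject —
  emulating the reported pattern in which the most distal sensor's coherence
  is inadequate and is excluded from analysis, while the remaining sensors
  are comfortably usable. The coherence decline is an emergent property of
  fixed noise plus attenuation, not imposed per sensor.

`natural_frequencies()` exposes the chain's undamped modes (about 200, 790,
1300, 1780, 2360, 3270 Hz; four inside the excited band). A
`single_mass_model()` reduction exists purely as a validation harness: its
resonance has the closed form $f_n = \frac{1}{2\pi}\sqrt{k/m}$, letting the
whole excitation→PEAK pipeline be checked against an analytic value.

## Excitation

"Randomized frequencies" is realized as a random-phase multisine: within
each pulse, every DFT-grid frequency in the excited band carries identical
spectral magnitude and an independent uniform phase, and the pulse is scaled
to the target force RMS. This makes the per-frequency excitation amplitude
constant by construction — exactly the condition under which a weakly
nonlinear biological system can be treated as a linear equivalent — and it
makes flatness of the input spectrum exact rather than approximate.
Band-limited random noise would have been a defensible alternative reading;
the multisine was chosen and is recorded here as an assumption. The static
5 N preload has no dynamic role in a linear model and is carried as metadata
only.

Because each pulse is periodic within its one-second segment, the simulator
synthesizes the response pulse-by-pulse in the frequency domain
(multiplication by the chain's acceleration FRF on the pulse DFT grid),
which is exact for this excitation — no transient leakage approximation is
involved. The chain's dynamic stiffness matrix is tridiagonal, so the
frequency sweep is solved by a vectorized Thomas algorithm; a dense
`solve()` serves as the independent cross-check in the tests, never as the
implementation.

## Spectral estimation

One pulse is one estimation segment (the protocol averages pulses, not
sliding windows). Per-pulse one-sided auto- and cross-spectral densities are
averaged across the ten pulses:

$$\hat S_{xx}(f) = \frac{1}{P}\sum_{p=1}^{P} \frac{2|X_p(f)|^2}{f_s \sum w^2},
\qquad
\hat S_{yx}(f) = \frac{1}{P}\sum_{p=1}^{P} \frac{2\,Y_p(f)X_p^*(f)}{f_s \sum w^2}.$$

The window is rectangular by default: the multisine is periodic in its
segment, so there is no leakage to taper away; a Hann option exists for
non-ideal recordings. The analysis grid is the DFT grid of one pulse (1 Hz
for the default protocol), restricted to the excited band — out-of-band bins
carry no input power and are never analyzed.

The FRF is the per-frequency ratio of output power to input power,
$\mathrm{FRF}(f) = \hat S_{yy}(f)/\hat S_{xx}(f)$ (an $|H|^2$-like
quantity). A magnitude convention ($\sqrt{\cdot}$) is available behind a
flag. PEAK is invariant to this choice because the square root is strictly
monotone; AUC and RMS are not, and the convention is therefore recorded in
every `spectral_set`. Magnitude-squared coherence is

$$\gamma^2(f) = \frac{|\hat S_{yx}(f)|^2}{\hat S_{xx}(f)\,\hat S_{yy}(f)} \in [0,1],$$

computed from the *averaged* spectra (single-segment coherence is
identically 1 and the code refuses to compute it). For an output completely
unrelated to the input, the expected coherence is approximately $1/P$ — with
$P = 10$ pulses, about 0.1 — which is the basis of one of the acceptance
checks.

The FRF is smoothed with a running median (default window: 5 bins; the
source protocol names a median filter but no kernel size). At the edges the
window shrinks symmetrically, so endpoints pass through unchanged; order
statistics remove isolated spectral spikes without biasing smooth regions
and preserve monotone runs.

## Outcomes and quality control

From each sensor's smoothed FRF: PEAK is the frequency of the global
maximum with ties broken toward the lowest frequency; AUC is the
trapezoidal integral over the in-band grid; RMS is the root of the mean
squared FRF value across bins. RMS has no universally fixed definition in
this context; it is computed here from the same smoothed FRF object as the
other two outcomes, across frequency bins, which keeps all three outcomes
functions of one curve.

A sensor is retained only if its in-band mean coherence reaches the QC
threshold (default 0.5, inclusive; the observed usable sensors sat at
0.71–0.83 and the excluded one at 0.15, so any threshold in between
separates them — 0.5 is the midpoint choice). Outcomes are averaged across
the three trials per subject; a sensor failing QC in *any* trial is dropped
for that subject entirely. This any-trial rule is stricter than the source
protocol states and was chosen so that every trial mean rests on the same
sensor set.

## Twin comparison

Within a pair, differences are signed as lower subject id minus higher —
a fixed, documented convention. Group-level inference per
group × outcome × sensor cell tests $H_0\!: \overline{\Delta} = 0$ with,
by default, the one-sample (paired) t-test on the pair differences; an
ANCOVA variant regresses the differences on an intercept plus mean-centered
pair-level covariates (default: pair-mean BMI, the anthropometric the
protocol discusses) and tests the intercept. Both are available because the
source analysis names ANCOVA in its methods while its results table reports
paired t-tests; the paired t is the default and every report records the
method used. P-values are two-sided and uncorrected (matching how the
original per-cell values were reported); a Bonferroni option exists, off by
default. Pair differences with zero variance yield p = 1 with a warning
rather than an error.

## The synthetic cohort

`generate_twin_cohort()` emulates the study design: each pair perturbs the
default chain with between-pair variability (lognormal factors, CV 10%),
each twin adds an independent within-pair perturbation (CV 2%), and in
discordant pairs exactly one twin receives a localized alteration — by
default, halving the link stiffness above L2 (a "compression fracture").
Both twins of a pair are excited with the same pulse trains (one session
per trial), so with zero variability and zero noise twins produce
bit-identical responses. Three seeded RNG streams (model perturbation,
excitation phases, measurement noise) derive from one master seed, making
cohorts fully reproducible.

The alteration is assigned to the *second* twin of each pair. With the sign
convention above, the within-pair difference then has a consistent sign
across pairs, which is what gives the group mean-difference test something
to detect; if the altered twin were randomized, mean differences would
vanish by symmetry even when every pair's magnitude is large. The real
roster contains affected twins in both positions; this is a deliberate
simplification of the generator, not a property of the analysis code, which
is sign-agnostic.

### What the generator does and does not emulate

It emulates: constant-amplitude in-band excitation; resonances that move
under localized stiffness change; soft-tissue attenuation growing with
distance; the coherence decline that disqualifies the most distal sensor;
biological inter-twin variability; trial-to-trial measurement noise.

It does not emulate: nonlinear tissue mechanics, skin-marker motion
artifacts beyond additive noise, sensor reattachment variability,
frequency-dependent tissue filtering, or pathology-specific FRF
"fingerprints". One visible consequence: the synthetic alteration changes
the FRF's overall level as well as its peak location, so AUC and RMS also
reach significance in synthetic discordant cohorts, whereas the in-vivo
study found only PEAK responsive. Passing the synthetic checks therefore
shows the *pipeline* behaves correctly under known ground truth; it does
not by itself establish how the outcomes rank on real spines.

## Numerical choices and degenerate inputs

* Frequency grid: DFT grid of one pulse; band edges are resolved inclusively
  with a $10^{-9}$ relative tolerance.
* Coherence is clamped to $[0,1]$ only within $10^{-9}$ numerical slack;
  larger excursions raise an error rather than being hidden.
* FRF computation refuses bins whose input power is below $10^{-20}$ of the
  in-band maximum (effectively unexcited bins).
* PEAK tie-break: lowest frequency. Median-filter edge rule: symmetric
  shrinking window. Zero-variance difference vectors: p = 1 with warning.
* Determinism: all randomness flows through explicit seeds; identical seeds
  give bit-identical excitation, models, noise, and therefore results.

## Problem sizes used in the shipped checks

The test suite and the acceptance script regenerate everything they check.
The cohort-level checks use the study's own design — 5 concordant plus 5
discordant pairs, three trials each — with 50 replicates for the detection
(power) arm, 200 concordant-only replicates for the type-I arm, and 20
seeded pairs for the attenuation-ordering check; smaller unit fixtures use
shortened pulse trains. At these sizes the nominal-α behavior of the
concordant arm is resolved to a binomial standard error of well under 0.02,
and the full run completes in minutes on a single core.

## Known limitations

* The chain is linear by construction; the "linear equivalent" assumption of
  the protocol is imposed, not tested.
* Attenuation is a frequency-independent gain per sensor; real soft tissue
  filters high frequencies preferentially.
* The ANCOVA covariate set is configurable but defaults to pair-mean BMI
  only.
* Synthetic effect sizes are set by the alteration's stiffness factor;
  they are not calibrated to any specific pathology.
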