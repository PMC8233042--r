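---
title: "Mapping optokinetic response tuning across the visual field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping optokinetic response tuning across the visual field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okrsphere)
```

## The scientific problem

Larval zebrafish stabilise their gaze with the optokinetic response (OKR):
slow eye movements track large moving patterns, interleaved with resetting
quick phases (saccades). Because the larva's visual field spans almost the
whole sphere, asking *where* in the visual field motion drives the OKR most
strongly requires a display that surrounds the animal — a spherical arena of
flat square LED tiles — and an analysis that lives naturally on the sphere.
`okrsphere` implements that analysis: from the geometry of the arena and of
disk-cropped grating stimuli, through gain estimation on raw eye traces, to
spherical tuning maps, asymmetry decompositions, and permutation inference.
A seeded synthetic-data generator stands in for the animal, so the entire
chain is testable and reproducible on a desk.

## Coordinates and arena geometry

Directions are fish-centred geographic coordinates: azimuth `α ∈ [−180°,
180°]`, positive to the animal's right, elevation `β ∈ [−90°, 90°]`,
positive above, with (0°, 0°) directly rostral. The Cartesian frame is
x = right, y = rostral, z = up, so `u = (cos β sin α, cos β cos α, sin β)`.
Azimuth ±180° is normalised to +180° and the azimuth at the poles is fixed
at 0°, making round trips deterministic. Public interfaces use degrees
throughout; radians appear only inside trigonometric kernels.

Three closed-form coverage quantities describe the arena:

* a spherical cap of half-angle θ covers `(1 − cos θ)/2` of the sphere —
  `cap_fraction(90) = 50%`, `cap_fraction(60) = 25%`;
* the latitude band within ±69° (the arena minus its two polar holes)
  covers `cos 21° = 93.36%`;
* removing the 30°-wide LED-free keel strip leaves
  `93.36% × 330/360 = 85.58%`.

The solid angle of one flat tile of edge `D` mounted at radius `R_S` is
computed by numerical quadrature of the central projection,
`Ω = ∬ (1 + x² + y²)^{−3/2} dx dy` over `|x|,|y| ≤ tan(atan(D/2R_S))`,
and agrees with the rectangular-pyramid closed form to better than 1e−6 sr.
For `D = 21 mm`, `R_S = 106.5 mm` this gives 0.0385 sr per tile and a
strict tiled coverage of `232 Ω / 4π ≈ 71%` for the 232-tile arena.
Published descriptions of this arena quote a smaller strict coverage
(66.5%); that figure is not reproducible from the same per-tile formula and
dimensions, so `arena_coverage()` reports the computed value and the
discrepancy is documented rather than hidden. The tile layout itself
(`arena_model()`) is procedural — rings of constant latitude packed without
overlap and trimmed to 232 tiles — reproducing the counts and angular scale
of the physical arena, not its CAD file.

## Stimulus design

Stimuli are vertical bars bounded by true meridians (elevation-independent
in azimuth), drifting horizontally with sinusoidal velocity
`v(t) = A_v sin(2πft)`; integrating gives the position
`s(t) = a_S(1 − cos 2πft)` with amplitude `a_S = A_v/2πf`. The defaults —
0.06 cycles/degree, `A_v = 12.5 °/s`, `f = 0.1 Hz`, 100 s per phase —
give `a_S ≈ 19.9°`. The bars form a 50%-duty square wave, the natural
choice for a binary LED display. A stimulus is restricted to a disk by a
permanently dark surround: lit only within a great-circle half-angle of the
crop centre.

The 38 stimulus-centre directions are generated, not tabulated. Seven seeds
populate one eighth of the sphere — one fixed at (90°, 0°), two constrained
to the lateral meridian, one to the equator, three free — and their images
under the sagittal, horizontal and coronal mirror planes complete the set
(orbit sizes 2, 4, 4 and 8: `3×8 + 2×4 + 1×4 + 1×2 = 38`). The seeds then
repel each other until a stable pattern emerges. Two implementation choices
matter:

* **Exact symmetry by construction.** Only the 7 fundamental seeds are free
  variables; the other 31 are regenerated by reflection at every step. In
  Cartesian coordinates the three reflections are sign flips of x, z and y,
  which makes the orbit expansion trivial and exact.
* **Short-range repulsion.** The pair energy is `1/chord^p` with `p = 6` by
  default. The long-range Coulomb energy (`p = 1`) leaves the closest pair
  of the converged set at about 29.7° separation; the steeper default
  pushes the equilibrium to just above 30°, which better matches the
  near-equidistant design goal. The exponent is a parameter.

Descent is a backtracking gradient step on the free parameters, so the
logged energy trajectory is monotonically non-increasing; three random
starts guard against local minima, and final coordinates are rounded to
0.1°. Typical runtime is a few seconds.

## Gain estimation from eye traces

Saccades are detected on a Savitzky–Golay-smoothed velocity trace
(threshold 40 °/s, events merged within 0.5 s, padded by 0.1 s; all
configurable — the thresholds are this package's own, since eye-tracking
pipelines rarely publish theirs). The segments between saccades (ISIs) are
fitted jointly with one shared sinusoid and one offset per segment:

```
f(t ∈ ISI_k) = −c₁ cos(c₂ t + c₃) + c_{k+3}
```

For fixed `c₂` this model is *linear* in `(A, B, offsets)` after writing
`−c₁ cos(c₂t + c₃) = A cos(c₂t) + B sin(c₂t)`, so the fit profiles the
linear part with `lm.fit` and optimises only `c₂`, softly bounded within
±20% of the known stimulus envelope frequency. The frequency is fitted
rather than fixed because real traces show small frequency wobble, but the
known stimulus frequency is too informative to ignore — hence the bounded
search rather than a free one. Amplitudes are sign-normalised (`c₁ ≥ 0`,
compensated in `c₃`). On noiseless model traces this recovers all
parameters to machine precision; with 0.1–0.2° of measurement noise on a
100-s trace the gain estimate is unbiased with a typical error of 1–2%,
though saccade-heavy trials (Poisson draws of 35+ quick phases) can reach
~6%.

The OKR gain is `g = c₁/a_S`; the Bode point is the pair (gain, phase)
with the phase `c₃` referenced to the stimulus position
`s(t) = −a_S cos(2πft)` and wrapped to (−180°, 180°].

Trial quality control mirrors experimental practice of excluding trials
contaminated by other behaviours: a trial is rejected when the residual
drift slope (regressed within ISIs, so per-ISI offsets cannot mask it)
exceeds 0.2 °/s, or when the fit's R² falls below 0.3. Drift is checked
first: a drifting trial also has poor R², but the drift is the more
informative label. Both thresholds are package defaults, configurable in
`pipeline_config()`, and every exclusion is recorded with its reason.

## The spatial tuning model

Gain over the sphere is modelled as the sum of two von Mises–Fisher
components and an offset,

```
F(ξ) = Σ_{j=1,2} C_j κ_j exp(κ_j μ_jᵀ ξ) / (2π (e^{κ_j} − e^{−κ_j})) + C₃
```

one component per hemisphere because the yoked eyes each contribute a
preferred location. With this normalisation the offset-free surface
integrates exactly to `C₁ + C₂` over the sphere — a property the test
suite verifies by quadrature. Components are evaluated in the log domain,
so concentrations up to κ ≈ 700 remain finite.

Fitting is least squares on per-position aggregated gains (median across
fish and repetitions by default, mirroring the arena-rotation correction;
per-record fitting is available via `aggregate = "none"`). The optimiser is
Levenberg–Marquardt with five starts: the canonical start places the
components at the mirror-symmetric lateral positions (±90°, 0°) with κ = 5,
the rest are seeded perturbations of it. Two summaries are reported
deliberately: the component centres μ (centres of mass of each mode) and
the numerically located maxima of F, which drift apart when the modes
overlap.

Environmental asymmetries are cancelled by the rotated-arena protocol:
positions from the rotated dataset are remapped to fish-centred
coordinates by `(α, β) → (−α, −β)` (from the fish's perspective the
rotation swaps left/right and upper/lower), medians are taken per position
within each dataset, and the two medians are averaged. Any additive bias
that is odd in the arena orientation cancels exactly in expectation. The
remap is a configurable function, since the appropriate mapping depends on
how the physical rotation was performed.

Tuning curves in frequency and size are fitted per stimulus location:
a log-Gaussian bump for spatial frequency (peak reported alongside the raw
argmax, with flat and boundary-peak profiles flagged rather than trusted)
and a sigmoid in log size, `g(s) = g_max / (1 + exp(−(ln s − ln s50)/w))`,
whose half-maximum size `s50` is the headline parameter. The sigmoid's
`s50` is bounded within the sampled size range and its slope kept positive;
sizes must span at least a decade. Whether a stimulus counts as directly
visible to an eye uses the measured mean eye axes (−84.8°, 3.5°) and
(80.1°, 4.9°) and a per-eye field of view of 163° (a literature value for
young larvae; it is a parameter because its exact value at this age is not
settled): direct if the centre lies within `fov/2 + crop half-angle` of the
axis.

## Asymmetry statistics and permutation inference

The yoking index `Y = (g_L − g_R)/(g_L + g_R)` compares the two eyes
within a stimulus phase; the bias index `B = (m_L − m_R)/(m_L + m_R)`
compares hemifield medians within a fish, with stimuli exactly on the
sagittal plane excluded from both pools. Each fish's bias decomposes as
`B_k = φ b₁ + b₂ + b₃,ₖ + η`, with φ = ±1 encoding the arena orientation.
The system is underdetermined (n + 2 coefficients for n fish), so the fit
is two-stage: assuming individual biases average out, `b₁` and `b₂` come
from a first regression of B on [φ, 1]; each `b₃,ₖ` is then the fish's
mean residual. At zero noise this recovers the generating coefficients to
machine precision; with noise, the reported standard errors have close to
nominal coverage.

The permutation test treats fish as exchangeable units. For two groups
(e.g. upright versus upside-down embedding) the default statistic fits the
pooled bimodal vMF surface per group, averages the two hemisphere
elevations, and takes the group difference; the statistic is a function
argument, so cheaper or different statistics plug in directly. All label
assignments preserving the group sizes are enumerated exactly up to 20
fish — a 3-vs-7 split gives `choose(10,3) = 120` assignments — with seeded
Monte-Carlo sampling above that. The p-value counts assignments (including
the identity) whose statistic is at least the observed one, so `p ≥ 1/P`
and the test is valid by construction; permutations in which the statistic
fails (degenerate fits) are excluded and counted.

## The synthetic-data generator

`okr_ground_truth()` fixes a complete generative model; `generate_dataset()`
turns it into gain records and, optionally, raw 60-Hz traces:

| parameter | default | role |
|---|---|---|
| vMF centres | (−82.5°, 5.1°), (81.7°, 1.6°) | measured preferred locations |
| κ | 8 | tuning width (~23° half-width at half-height) |
| peak gain | 0.3 | scale of the surface; arbitrary but realistic for fast stimuli |
| Y0 | 0.2 | yoking index, matching the reported monocular value |
| b₁, b₂, σ_b3 | 0, 0, 0.01 | asymmetry machinery, off by default |
| gain noise sd | 20% of peak | per-record gain variability |
| trace noise | 0.1° | eye-tracker noise |
| saccade rate | 0.25 Hz | Poisson quick phases, amplitude N(8°, 2°) truncated > 0 |
| drift prob. | 0 | optional trial contamination for QC testing |

Hemispheric bias is multiplicative — left-hemisphere stimuli are scaled by
`(1 + a)` and right-hemisphere by `(1 − a)` with `a = φb₁ + b₂ + b₃,ₖ` —
so the ratio-based bias index recovers `a` to first order; an additive
variant would couple the recovered bias to the local gain level. The
unstimulated eye receives `g (1 − Y0)/(1 + Y0)`, which makes the empirical
yoking index converge to Y0 exactly. Quick phases are directed against the
instantaneous stimulus velocity and smeared over ~50 ms, as real saccades
are.

What the generator does *not* emulate: eye-plant dynamics (slow phases are
pure scaled sinusoids, so phase lags are zero unless injected), blinking
and tracking dropouts, gain drift within a session, binocular rivalry
effects at the edges of the two monocular fields, and pixelation of the
stimulus by the LED grid. Passing tests therefore demonstrate that the
estimators recover the parameters of this model class under realistic
noise — not that the model class captures every property of real traces.

## Numerical choices and study conditions used in the tests

* Piecewise-sinusoid recovery is asserted to 1e−6 on noiseless traces; the
  profiled linear solve makes this achievable at any SNR the optimiser's
  1e−10 frequency tolerance supports.
* vMF recovery is tested on cohorts of 7 fish × 38 positions × 2
  repetitions with gain noise at 20% of peak; the median great-circle
  error of the recovered centres is required to stay below 5°.
* The size-tuning Monte-Carlo uses the same cohort sampling (14 records per
  size) and a generator slope of `w = 0.7` natural-log units — the curve
  rises over about a decade and a half, consistent with published
  descriptions; with a single record per size, `s50` is statistically
  under-determined at this noise level and no estimator would meet the
  tolerance.
* Permutation calibration runs 200 seeded null simulations of an 8-fish
  4-vs-4 split with a per-fish mean-elevation statistic; the fraction of
  p ≤ 0.05 must not exceed 0.075.
* The repulsion placement, vMF fits and permutation enumeration together
  keep the full test suite under two minutes on one CPU; problem sizes in
  the tests (cohort counts, numbers of seeds and replicates) were chosen as
  the smallest at which the statistical assertions are stable.

## Known limitations

* The procedural tile layout reproduces counts and coverage, not the exact
  physical LED positions; analyses that depend on individual LED placement
  (e.g. pixelation studies near the poles) need the CAD-derived table.
* The bimodal vMF surface cannot represent ring-shaped or more-than-bimodal
  tuning; the kernel-smoothed map is the model-free complement.
* `correct_arena_rotation` assumes the rotated protocol sampled the same
  fish-centred positions after remapping; unmatched positions are dropped
  (and reported) rather than interpolated.
* The permutation test's default statistic refits the vMF surface per
  assignment, which is exact but slow for large enumerations; supply a
  cheaper statistic when the split is large.
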