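---
title: "Modelling and quantifying ferroptotic ROS trigger waves"
author: "ferrowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and quantifying ferroptotic ROS trigger waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferrowave)
```

## The system

Ferroptosis — iron- and lipid-peroxidation-dependent cell death — can spread
across a cell monolayer for millimetres at a constant speed of a few µm/min.
Constant-speed, constant-amplitude propagation is the signature of a
*trigger wave* in a bistable medium, not of diffusion, whose reach grows only
as $\sqrt{2Dt}$ (compare both with `diffusionDistance()`). The propagating
signal is reactive oxygen species (ROS): cells under ferroptotic stress
(erastin, an inhibitor of cystine uptake) become bistable in their ROS
balance, and ROS diffusing from a dying cell can push its neighbour over the
activation threshold, regenerating the front cell by cell.

`ferrowave` implements the computational side of this picture end to end:
the single-cell ROS model and its bifurcation analysis, a lattice
reaction–diffusion simulator with photoinduction and a death rule, seeded
generators of synthetic time-lapse data, the image quantifications
(kymographs, wave speed, outlines, wavefront width/amplitude, death-vector
entropy, initiation-site statistics, orientation entropy, lipid-peroxidation
ratio), and the parametric dose–response and gap-crossing fits.

## The single-cell ROS model

The cellular ROS balance has four terms (units: µM, min):

$$
\frac{d\,\mathrm{ROS}}{dt} =
  \underbrace{k_{pos}\frac{\mathrm{ROS}^{n}}{EC50_{pos}^{n}+\mathrm{ROS}^{n}}}_{\text{positive feedback}}
  \;-\;
  \underbrace{k_{d}\,\phi(E)\,
  \frac{EC50_{d}^{m}}{EC50_{d}^{m}+\mathrm{ROS}^{m}}\,\mathrm{ROS}}_{\text{GSH-mediated removal}}
  \;-\; k_{deg}\,\mathrm{ROS} \;+\; k_{synth},
$$

with Hill coefficients $n = m = 3$. The positive feedback lumps the Fenton
reaction and NADPH-oxidase signalling into a single term. Erastin weakens
the glutathione arm through

$$
\phi(E) = \frac{c_{GSH} + \dfrac{EC50_{era}}{EC50_{era}+E}}{1 + c_{GSH}},
$$

normalized so that $\phi(0) = 1$: $k_d$ is the removal rate constant in the
absence of erastin, and removal falls towards the floor
$c_{GSH}/(1+c_{GSH})$ set by cystine-independent GSH production as
$E \to \infty$. This normalization is required for the model to reproduce
the bistable window quoted below; without it both fold points shift up by
the same factor $1 + c_{GSH}$.

Defaults (`rosModelParams()`): $D = 178\ \mu m^2/min$, $k_{pos} = 1.2$,
$EC50_{pos} = 1$, $k_d = 1.5$, $c_{GSH} = 0.1$, $EC50_{era} = 0.27$,
$EC50_d = 2$, $k_{deg} = 0.26$, $k_{synth} = 0.1$, cell diameter 16 µm,
intercellular gap 5 µm.

### Steady states and bifurcation

`findSteadyStates()` locates all roots of the reaction rate on
$[0, 10]\ \mu M$ by a sign-change scan on a hybrid log/linear grid (512
points) refined by bisection to $|rate| < 10^{-10}$, with an extra guard
that refines local extrema of the rate to catch near-tangent root pairs
close to a fold. Stability comes from the analytic derivative
(`reactionRateDeriv()`, negative slope means stable), with a central
finite-difference fallback (step $10^{-6}$) if the analytic value is not
finite. `bifurcationScan()` counts roots along an erastin grid
(default step 0.01 µM over [0, 20]) and bisects each count change to
±0.005 µM, reporting the midpoint of the final bracket.

```{r bifurcation}
scan <- bifurcationScan(rosModelParams(), curveBy = NA)
c(lower = scan$eLower, upper = scan$eUpper)
```

Below the lower fold the balance is monostable low; between the folds a low
state, an unstable threshold state (USS) and a high state coexist; above the
upper fold only the high state survives. ROS excursions above the USS are
amplified to the high state — this is the cell-intrinsic amplifier that a
trigger wave needs.

## The spatial simulator

`runSimulation()` integrates the reaction–diffusion equation on a lattice
with one site per cell, $\Delta x = 21\ \mu m$ (cell diameter plus gap).
Design choices:

* **Boundaries** are no-flux (Neumann), matching a closed culture well.
* **Time stepping** is explicit Euler at 0.8 of the diffusion stability
  bound ($\Delta x^2/2D$ in 1D, $\Delta x^2/4D$ in 2D); the reaction is
  non-stiff at these rates, and the explicit update keeps every term
  inspectable. ROS is clamped at zero after each update (the clamp is
  inactive under the stability bound; it only guards round-off).
* **Initialization**: every site rests at the lower steady state of its
  erastin condition; photoinduction then raises a chosen region, by default
  to 1.05 × USS.
* **Death rule**: the death threshold is 90% of the upper steady state of
  the pre-photoinduction condition, held fixed. A site that has spent an
  accumulated 30 min at or above the threshold dies: its production terms
  ($k_{pos}$, $k_d$, $k_{synth}$) are set to zero while first-order
  degradation and diffusive exchange continue.
* **Front tracking**: the ROS front is the farthest site from the
  photoinduction centroid at or above the USS; on 2D sheets the 95th
  percentile of crossing-site distances is used to resist stragglers.
  Recording stops when the front comes within two sites of the boundary.

`measureSimSpeed()` fits the front trajectory over its last two thirds
(the default window) by least squares. On a 300-cell chain the front is
linear in time after a short transient ($R^2 > 0.999$), its speed is
insensitive to the photoinduction amplitude (any level above the USS gives
the same asymptotic speed within a fraction of a percent), monostable
conditions give a structured no-wave result, and counter-propagating fronts
annihilate on collision.

Two numerical caveats are worth knowing. First, at the physical lattice
spacing of 21 µm the front (intrinsic width $\sim\sqrt{D/k}\approx 13\ \mu m$)
is under-resolved, and the discrete medium propagates ~15% slower than the
continuum limit; halving the spacing recovers the continuum speed to within
a few percent (a real effect of discrete bistable media, kept because the
cell-scale lattice is the model's physical premise). Second, the
accumulated-exposure death clock can leave isolated sites just short of the
30 min mark when their neighbours die first and drain their ROS; the fronts
and speeds are unaffected, but the final dead fraction after a collision is
not exactly 100%.

## Synthetic data: what it emulates, and what it does not

The generators provide fully seeded, bit-reproducible fixtures with the
statistical structure the analyses assume:

* `generateWaveStack()` — a radial or planar death front expanding at
  constant speed (nuclear-dye step from baseline to baseline + rise when
  the front passes), and a Gaussian ROS band leading the death front by a
  configurable lag; additive Gaussian pixel noise. The death channel is a
  binary step rather than textured nuclei: every quantification here
  operates on intensity thresholds, not morphology.
* `generateRandomDeathStack()` — the spatially unordered null: death foci
  at uniform random positions and times.
* `generateInitiationSeries()` — per-position event counts Poisson with
  the study rate (defaults: 1.01 events per 5 h window across 756 positions
  of 1.26 × 1.26 mm²), times uniform on a 10 min acquisition clock, so
  pooled inter-event intervals are geometric on that clock.
* `generateDoseResponse()` — speeds from the Michaelian/biphasic models
  plus Gaussian noise; `generateDeathCentroids()` — per-frame newly-dead
  cell centroids around planted initiation sites with modest growth.

Passing tests on these fixtures shows the estimators are correct against a
known truth under controlled noise; it does not certify performance on real
microscopy, which adds illumination drift, debris, segmentation error and
spatially correlated noise that the generators deliberately omit.

## Image quantifications

* **Wave outlines** (`waveOutline()`): top-1% intensity binarization,
  disc dilation (3 px), mean filtering (5 px), re-binarization at 0.5. The
  dilation radius, filter size and the debris size filter of
  `frontIncrement()` (40 µm² minimum object area, applied to the
  consecutive-frame difference image) are exposed as arguments since no
  canonical values exist.
* **Kymographs** (`buildKymograph()`): per position along the propagation
  axis, the maximum signal over a 250 µm transverse band, stacked over
  frames. A 3 px box denoise per frame precedes the max projection — the
  maximum of raw i.i.d. pixel noise is an inflated extreme statistic, and
  a light average keeps the projection representative (set `denoise = 1`
  to disable).
* **Wave speed** (`estimateWaveSpeed()`): threshold at the kymograph's
  90th intensity percentile (shrunk by $10^{-8}$ of the range to tolerate
  float round-off on plateaus); per position the earliest crossing frame;
  per frame the 11 positions nearest the mode of the crossing-location
  histogram (1 px bins, ties toward the smaller coordinate); least-squares
  slope of position on time. A `frameRange` lets the caller split the fit
  at a known change-point (e.g. drug addition mid-movie). The top-10%
  threshold separates crossed from uncrossed territory only when the wave
  does not fill the whole kymograph, so validation movies are sized for
  the front to traverse about a third of the field — as in the real
  recordings.
* **Wavefront width and amplitude** (`frontWidthAmplitude()`): twelve rays
  from the wave origin; per ray the distance between consecutive outlines
  and the maximal ROS between them.
* **Intensity profiles** (`intensityProfile()`): transverse mean over
  250 µm, 50 µm moving average, optional min–max normalization with the
  convention that a constant profile maps to all zeros.
* **Death-vector fields** (`deathVectorField()`): both masks are smoothed
  (Gaussian, σ = 2 px); the direction is down the gradient of the combined
  death occupancy — from dead towards not-yet-dead territory — signed by
  the net growth, so reversing the frame order flips every vector by π;
  the magnitude is the absolute smoothed mask difference.
  `vectorEntropy()` is the Shannon entropy of the angle histogram (30 bins
  over 360°), 0 bits for a coherent front, at most $\log_2 30 \approx
  4.907$ bits for directionless death; a `region` mask restricts it to a
  neighbourhood (e.g. 100 × 350 µm) where even a curved front is locally
  planar.
* **Initiation sites** (`detectInitiationSites()`): a site needs strictly
  more than 5 newly dead cells within a 40 µm-radius circle at its first
  frame, and a first-to-last-frame growth of the local death count below
  20-fold (the growth window is a 200 µm radius; both configurable — the
  20-fold rule's time base is ambiguous and first-to-last is the adopted
  reading). `initiationStatistics()` compares observed counts against a
  seeded Monte-Carlo Poisson sample (N = 10⁵) with the observed mean via a
  two-sample Kolmogorov–Smirnov test, and pooled inter-event intervals —
  the per-position series concatenated in random order — against a
  geometric sample with the observed mean interval on the acquisition
  clock. Two-sample KS against a large reference sample reproduces the
  stated procedure without inventing a one-sample variant.
* **`palpRatio()`** — oxidized/(oxidized + reduced) probe fluorescence;
  **`orientationEntropy()`** — fibre-orientation entropy over 90 bins on
  0–180°.

## Curve fits

`fitMichaelianInhibition()` ($y = y_0 + (y_M - y_0)K/(K+x)$),
`fitMichaelianActivation()` ($y = y_0 + (y_M - y_0)x/(K+x)$) and
`fitBiphasicInhibition()`
($y = y_0 + y_M(1 - f_1\frac{x}{K_1+x} - (1-f_1)\frac{x}{K_2+x})$,
$0 \le f_1 \le 1$) use Levenberg–Marquardt least squares with
deterministic, data-driven starts ($y_0 = \min y$, $y_M = \max y$,
$K = \mathrm{median}\ x$; biphasic: $f_1 = 0.5$, $K_1$/$K_2$ at the dose
quartiles). Identifiability of the biphasic fit is enforced by ordering
$K_1 < K_2$ after the fit (swapping $f_1 \to 1-f_1$) and flagging
near-degenerate $K_1 \approx K_2$. Two-site parameters are only well
determined by log-dense dose designs that bracket both sites with
replicates; sparse designs recover the curve but not the site split.
`predictDose()` gives pointwise 95% bands by first-order (delta-method)
propagation of the parameter covariance — the band type is a package
choice, pointwise rather than simultaneous.

`fitLogisticGap()` fits $p(x) = 1/(1+e^{-(\beta_0+\beta_1 x)})$ to binary
gap-crossing outcomes by maximum likelihood and reports
$x_{50} = -\beta_0/\beta_1$, the gap width crossed half the time. Complete
separation (non-overlapping outcome classes, a glm failure, or a diverging
coefficient) switches to a lightly ridge-penalized likelihood
(penalty $10^{-4}\|\beta\|^2/2$) and is flagged.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 1D chains of 300 cells
(about 700 simulated minutes), validation stacks of up to ~600 × 31 px ×
80 frames, 50-seed replicate sets for the stochastic checks and 100-seed
sets for fit recovery; these sizes make every distributional claim testable
in minutes on a laptop while leaving the estimators' asymptotics visible.
All stochastic components take explicit integer seeds, and identical seeds
reproduce results bit for bit.

## Known limitations

* The lattice simulator under-resolves the front at the physical 21 µm
  spacing (see above); absolute simulated speeds carry a ~15%
  discretization deficit relative to the continuum.
* The death clock freezes for sites whose neighbours die first (mixed
  alive/dead steady states at late times after collisions).
* The synthetic imagery is a threshold-level abstraction of microscopy;
  morphology-dependent analyses cannot be validated against it.
* Biphasic dose–response parameters are reported even when weakly
  identified; check the covariance and the degeneracy flag before
  interpreting the site split.
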