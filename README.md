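# ferrowave

Bistable ROS reaction–diffusion modelling and trigger-wave image analysis
for ferroptosis.

Ferroptosis — iron- and lipid-peroxidation-dependent cell death — can
propagate across cell monolayers for millimetres at a constant speed of a
few µm/min. That behaviour is the signature of a **trigger wave**: cells
under ferroptotic stress become *bistable* in their reactive oxygen species
(ROS) balance, and ROS diffusing from a dying cell pushes its neighbour over
an activation threshold, regenerating the front cell by cell. `ferrowave`
is for quantitative cell biologists and modellers who want to simulate this
mechanism and quantify it in time-lapse data.

The core model is the single-cell ROS balance (µM, min)

    dROS/dt = k_pos · ROS³/(EC50_pos³ + ROS³)                       (positive feedback)
            − k_d · φ(E) · EC50_d³/(EC50_d³ + ROS³) · ROS           (GSH-mediated removal)
            − k_deg · ROS + k_synth,

where erastin `E` (the ferroptotic stressor) weakens glutathione-mediated
removal through `φ(E) = (c_GSH + EC50_era/(EC50_era + E))/(1 + c_GSH)`,
normalized so `φ(0) = 1`. Raising erastin carries the balance from a
monostable low-ROS regime into a bistable one — low state, unstable
threshold (USS), high state — and the spatial model (diffusion `D` on a
lattice with one site per cell) then supports self-regenerating ROS fronts,
with a death rule that kills a site after 30 min above 90% of the high
state.

The package covers, in Bioconductor-style S4:

* **Model analysis** — `reactionRate()`, `findSteadyStates()`,
  `bifurcationScan()` (saddle-node fold points over erastin).
* **Wave simulation** — `initField()`, `applyPhotoinduction()`,
  `stepField()`, `runSimulation()`, `measureSimSpeed()`,
  `measureFrontWidthAmplitude()`, `simToImageStack()`.
* **Synthetic time-lapse data** — seeded generators for wave stacks,
  random-death stacks, Poisson initiation series, dose–response tables and
  dead-cell centroids; TIFF/CSV + YAML sidecar I/O.
* **Image analysis** — `waveOutline()`, `frontIncrement()`,
  `buildKymograph()`, `estimateWaveSpeed()`, `intensityProfile()`,
  `frontWidthAmplitude()`, `deathVectorField()`, `vectorEntropy()`,
  `detectInitiationSites()`, `initiationStatistics()`, `palpRatio()`,
  `orientationEntropy()`.
* **Curve fits** — `fitMichaelianInhibition()`/`Activation()`,
  `fitBiphasicInhibition()`, `fitLogisticGap()` (gap-crossing probability),
  `diffusionDistance()`.

## Worked example

```r
library(ferrowave)
p <- rosModelParams()   # reference parameter set

# 1. Where is the bistable window?
scan <- bifurcationScan(p, curveBy = NA)
sprintf("bistable window: %.3f - %.3f uM erastin", scan$eLower, scan$eUpper)
#> "bistable window: 0.386 - 11.619 uM erastin"

findSteadyStates(5, p)
#> SteadyStateSet at erastin = 5 µM: 3 state(s)
#>   ROS = 0.258377 µM (stable)
#>   ROS = 0.492784 µM (unstable)
#>   ROS = 4.68767 µM (stable)

# 2. Simulate a wave on a 300-cell chain at 5 µM erastin
sim <- runSimulation(5, p, c(1, 300), photoRegion = 1:10, tEnd = 700)
measureSimSpeed(sim)
#> SpeedEstimate: 8.935 ± 0.0047 µm/min (R² = 1.0000, 93 points)

# 3. Recover a known speed from noisy synthetic microscopy
st <- generateWaveStack(5.5, origin = c(150, 0),
                        geometry = stackGeometry(480, 31, 10, 15, 20),
                        noiseSd = 0.2, seed = 1)
estimateWaveSpeed(buildKymograph(st$death, axisIndex = 16))
#> SpeedEstimate: 5.384 ± 0.088 µm/min (R² = 0.9617, 150 points)

# 4. Are spontaneous initiations Poisson?
ev <- generateInitiationSeries(1.01, nPositions = 756, window = 5, seed = 1)
s <- initiationStatistics(ev, seed = 1)
sprintf("count KS p = %.3f; interval KS p = %.3f (mean %.2f h)",
        s$countTest$p, s$intervalTest$p, s$intervalTest$meanIntervalH)
#> "count KS p = 0.994; interval KS p = 0.700 (mean 4.90 h)"
```

Reading the numbers: the steady-state scan puts the monostable-to-bistable
fold near 0.39 µM erastin and the return to (high-state) monostability near
11.7 µM. At 5 µM the simulated front advances linearly at 8.9 µm/min after
a short transient. The kymograph estimator recovers the generator-truth
5.5 µm/min within ~2% despite pixel noise at 20% of the intensity step, and
the initiation statistics are consistent with a homogeneous Poisson process
(counts) with geometric inter-event intervals, as expected for independent
stochastic initiations.

See the vignette (`vignettes/ferrowave-methods.Rmd`) for the model's
assumptions, every tunable parameter with units and defaults, numerical
choices, and known limitations.

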