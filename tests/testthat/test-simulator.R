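test_that("initField rests every site at the lower steady state", {
  f0 <- initField(0, defaultParams, c(1, 40))
  root <- rosValues(findSteadyStates(0, defaultParams))
  expect_equal(unique(as.vector(rosValues(f0))), root, tolerance = 1e-9)

  f1 <- initField(1, defaultParams, c(1, 40))
  ss <- findSteadyStates(1, defaultParams)
  expect_equal(unique(as.vector(rosValues(f1))), rosValues(ss)[1],
               tolerance = 1e-9)
  expect_lt(max(rosValues(f1)), rosValues(ss)[2])  # strictly below the USS
  expect_true(all(aliveMask(f1)))
})

test_that("1D chains initialize identically under transposition", {
  a <- initField(1, defaultParams, c(1, 30))
  b <- initField(1, defaultParams, c(30, 1))
  expect_identical(rosValues(a), t(rosValues(b)))
})

test_that("initField refuses the monostable-high regime", {
  expect_error(initField(20, defaultParams, c(1, 10)), "no low steady state")
})

test_that("photoinduction validates its region and regime", {
  f <- initField(1, defaultParams, c(1, 30))
  expect_error(applyPhotoinduction(f, integer(0)), "empty")
  g <- applyPhotoinduction(f, 1:3)
  expect_equal(as.vector(rosValues(g))[1:3], rep(1.05 * g@uss, 3))
  expect_equal(rosValues(g)[, 4:30], rosValues(f)[, 4:30])
  fm <- initField(0.1, defaultParams, c(1, 30))
  expect_error(applyPhotoinduction(fm, 1:3), "monostable")
})

test_that("diffusion-only stepping conserves total ROS under no-flux walls", {
  set.seed(7)
  for (shape in list(c(1, 60), c(12, 15))) {
    f <- initField(1, defaultParams, shape)
    f@ros <- matrix(stats::runif(prod(shape), 0, 2), shape[1], shape[2])
    tot0 <- sum(rosValues(f))
    dt <- 0.8 * stableTimeStep(f, defaultParams)
    for (i in 1:100) f <- stepField(f, dt, defaultParams, reactionOn = FALSE)
    expect_equal(sum(rosValues(f)), tot0, tolerance = 1e-12)
  }
})

test_that("a uniform field at a stable steady state is a fixed point", {
  f <- initField(1, defaultParams, c(1, 50))
  start <- rosValues(f)[1, 1]
  dt <- 0.8 * stableTimeStep(f, defaultParams)
  for (i in 1:100) f <- stepField(f, dt, defaultParams)
  expect_lt(max(abs(rosValues(f) - start)), 1e-8)
  expect_true(all(aliveMask(f)))
})

test_that("time steps beyond the stability bound are refused by name", {
  f <- initField(1, defaultParams, c(1, 30))
  bound <- stableTimeStep(f, defaultParams)
  expect_error(stepField(f, 2 * bound, defaultParams), "stability bound")
})

test_that("sub-threshold perturbations decay back to rest", {
  f <- initField(5, defaultParams, c(1, 80))
  f <- applyPhotoinduction(f, 40, level = 0.9 * f@uss)
  dt <- 0.8 * stableTimeStep(f, defaultParams)
  peak0 <- max(rosValues(f))
  for (i in seq_len(ceiling(200 / dt))) f <- stepField(f, dt, defaultParams)
  expect_lt(max(abs(rosValues(f) - f@lowerSS)), 1e-4)
  expect_lt(max(rosValues(f)), peak0)
})

test_that("supra-threshold photoinduction launches a travelling wave", {
  sim <- runSimulation(5, defaultParams, c(1, 150), 1:5, tEnd = 250)
  tr <- sim@frontTrajectory
  expect_gt(max(tr$front, na.rm = TRUE), sim@photoRadius + 500)
  est <- measureSimSpeed(sim)
  expect_identical(est@status, "ok")
  expect_gt(waveSpeed(est), 0)
})

test_that("the death rule kills sites after sustained exposure, irreversibly", {
  sim <- runSimulation(5, defaultParams, c(1, 60), 1:5, tEnd = 120,
                       snapshotEvery = 20)
  deadCounts <- vapply(sim@snapshots, function(s) sum(!aliveMask(s)),
                       numeric(1))
  expect_gt(utils::tail(deadCounts, 1), 0)
  expect_true(all(diff(deadCounts) >= 0))  # death never reverts
  expect_true(all(vapply(sim@snapshots,
                         function(s) all(rosValues(s) >= 0), logical(1))))
  # first deaths appear only after the 30 min exposure clock
  firstDeath <- which(deadCounts > 0)[1]
  expect_gt(sim@snapshots[[firstDeath]]@time, 30)
})

test_that("front positions never retreat once the wave is launched", {
  sim <- runSimulation(5, defaultParams, c(1, 150), 1:5, tEnd = 250)
  tr <- sim@frontTrajectory
  expect_true(all(diff(tr$front[!is.na(tr$front)]) >= 0))
})

test_that("measureSimSpeed recovers an exact synthetic trajectory", {
  t <- seq(0, 300, by = 5)
  res <- new("WaveSimResult", snapshots = list(),
             frontTrajectory = data.frame(t = t, front = 5.5 * t),
             deathTrajectory = data.frame(t = t, front = NA_real_),
             photoCentroid = c(0, 0), photoRadius = 10,
             frontThreshold = 1)
  expect_equal(waveSpeed(measureSimSpeed(res)), 5.5, tolerance = 1e-12)

  set.seed(3)
  noisy <- res
  noisy@frontTrajectory$front <- 5.5 * t + stats::rnorm(length(t), sd = 2)
  est <- measureSimSpeed(noisy)
  expect_lt(abs(waveSpeed(est) - 5.5), 3 * est@stderr)
})

test_that("measureSimSpeed reports no-wave when the front stays home", {
  sim <- runSimulation(0.1, defaultParams, c(1, 100), 1:5, tEnd = 150,
                       photoLevel = 1)
  expect_identical(measureSimSpeed(sim)@status, "no-wave")
})

test_that("asymptotic speed converges under grid refinement", {
  half <- rosModelParams(cellDiameter = 8, intercellularDistance = 2.5)
  quarter <- rosModelParams(cellDiameter = 4, intercellularDistance = 1.25)
  s1 <- waveSpeed(measureSimSpeed(
    runSimulation(5, half, c(1, 400), 1:14, tEnd = 350)))
  s2 <- waveSpeed(measureSimSpeed(
    runSimulation(5, quarter, c(1, 800), 1:28, tEnd = 350)))
  expect_lt(abs(s2 - s1) / s1, 0.05)
})

test_that("simulation snapshots convert to a calibrated image stack", {
  sim <- runSimulation(5, defaultParams, c(1, 120), 1:5, tEnd = 200,
                       snapshotEvery = 25)
  st <- simToImageStack(sim)
  expect_s4_class(st, "ImageStack")
  expect_equal(pixelSize(st), 21)
  expect_equal(frameInterval(st), 25, tolerance = 0.05)
  expect_identical(channelName(st), "ros")
})
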