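# image quantifications: outlines, kymographs, profiles, vectors, entropies,
# initiation sites and event statistics

test_that("waveOutline traces a step front to within one pixel", {
  g <- stackGeometry(120, 60, 10, 15, 30)
  st <- generateWaveStack(5.5, origin = c(300, 0), geometry = g, seed = 1)
  m <- waveOutline(st$death, 15, dilateRadius = 0, filterSize = 1)
  co <- which(m, arr.ind = TRUE)
  r <- max(sqrt(((co[, 2] - 1) * 10 - 300)^2 + ((co[, 1] - 1) * 10)^2))
  expect_lt(abs(r - 5.5 * 14 * 15), 10)  # one 10 µm pixel
})

test_that("waveOutline on a flat frame warns and returns an empty mask", {
  st <- new("ImageStack", frames = array(0, c(20, 20, 2)), pixelSize = 10,
            frameInterval = 15, channel = "death")
  expect_warning(m <- waveOutline(st, 1), "flat")
  expect_false(any(m))
})

test_that("outline area grows monotonically for an expanding wave", {
  g <- stackGeometry(100, 100, 10, 15, 20)
  st <- generateWaveStack(4, origin = c(500, 500), geometry = g, seed = 1)
  areas <- vapply(seq(3, 8),
                  function(k) sum(waveOutline(st$death, k)), numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("frontIncrement tracks only the moving band", {
  g <- stackGeometry(100, 100, 10, 15, 12)
  st <- generateWaveStack(5, origin = c(500, 500), geometry = g, lag = 30,
                          seed = 1)
  m <- frontIncrement(st$ros, 6)
  co <- which(m, arr.ind = TRUE)
  r <- sqrt(((co[, 2] - 1) * 10 - 500)^2 + ((co[, 1] - 1) * 10 - 500)^2)
  truthR <- 5 * (5 * 15 + 30)  # ROS band radius at frame 6
  expect_lt(abs(stats::median(r) - truthR), 100)
  expect_error(frontIncrement(st$ros, 1), ">= 2")
})

test_that("identical consecutive frames give an empty increment", {
  fr <- array(stats::runif(20 * 20), c(20, 20, 2))
  fr[, , 2] <- fr[, , 1]
  st <- new("ImageStack", frames = fr, pixelSize = 10, frameInterval = 15,
            channel = "ros")
  expect_false(any(frontIncrement(st, 2)))
})

test_that("pure-noise differences are removed by filtering", {
  set.seed(8)
  fr <- array(stats::rnorm(60 * 60 * 2, mean = 1, sd = 0.05), c(60, 60, 2))
  st <- new("ImageStack", frames = abs(fr), pixelSize = 3,
            frameInterval = 15, channel = "ros")
  m <- frontIncrement(st, 2, dilateRadius = 0, filterSize = 3)
  expect_equal(sum(m), 0)
})

test_that("a width-one kymograph is a line profile", {
  g <- stackGeometry(60, 30, 10, 15, 10)
  st <- generateWaveStack(5, origin = c(150, 0), geometry = g,
                          noiseSd = 0.05, seed = 2)
  k <- buildKymograph(st$death, 16, width = 10, denoise = 1)
  expect_equal(kymoMatrix(k)[, 4], frames(st$death)[, 16, 4])
})

test_that("kymographs are invariant to stack transposition", {
  g <- stackGeometry(60, 40, 10, 15, 8)
  st <- generateWaveStack(5, origin = c(200, 0), geometry = g,
                          noiseSd = 0.02, seed = 3)
  fr <- frames(st$death)
  stT <- new("ImageStack", frames = aperm(fr, c(2, 1, 3)), pixelSize = 10,
             frameInterval = 15, channel = "death")
  k1 <- buildKymograph(st$death, 21, width = 150)
  k2 <- buildKymograph(stT, 21, width = 150, direction = "col")
  expect_equal(kymoMatrix(k1), kymoMatrix(k2))
})

test_that("wave speed is recovered and scales linearly", {
  st <- makeSpeedStack(5.5)
  e <- estimateWaveSpeed(buildKymograph(st$death, 16))
  expect_lt(abs(waveSpeed(e) - 5.5), 0.05)

  st2 <- makeSpeedStack(11)
  e2 <- estimateWaveSpeed(buildKymograph(st2$death, 16))
  expect_equal(waveSpeed(e2) / waveSpeed(e), 2, tolerance = 0.01)
})

test_that("piecewise speeds are recovered with split fit windows", {
  # mimics slowing of the wave after iron chelation: 5.28 then 2.33 µm/min
  dy <- 10; dt <- 15; nPos <- 400; nT <- 50; change <- 25
  tmin <- (seq_len(nT) - 1) * dt
  r <- ifelse(tmin <= tmin[change], 5.28 * tmin,
              5.28 * tmin[change] + 2.33 * (tmin - tmin[change]))
  m <- outer(seq_len(nPos), seq_len(nT),
             function(y, tt) 0.1 + ((y - 1) * dy <= r[tt]))
  k <- new("Kymograph", matrix = m, dy = dy, dt = dt, widthUsed = dy)
  e1 <- estimateWaveSpeed(k, frameRange = c(2, change))
  e2 <- estimateWaveSpeed(k, frameRange = c(change + 1, nT))
  expect_equal(waveSpeed(e1), 5.28, tolerance = 0.02)
  expect_equal(waveSpeed(e2), 2.33, tolerance = 0.02)
})

test_that("no-wave kymographs are reported as such", {
  m <- matrix(0.1, 50, 10)
  m[1:2, ] <- 1  # static bright corner, no propagation
  k <- new("Kymograph", matrix = m, dy = 10, dt = 15, widthUsed = 10)
  e <- estimateWaveSpeed(k)
  expect_identical(e@status, "no-wave")
})

test_that("intensity profiles average, smooth and normalize as specified", {
  fr <- array(1.5, c(80, 40, 1))
  st <- new("ImageStack", frames = fr, pixelSize = 10, frameInterval = 15,
            channel = "ros")
  flat <- intensityProfile(st, 1, 20, width = 250, smooth = 50)
  expect_true(all(abs(flat$intensity - 1.5) < 1e-12))
  # constant profile normalizes to all zeros by convention
  flatN <- intensityProfile(st, 1, 20, normalize = TRUE)
  expect_true(all(flatN$intensity == 0))

  fr2 <- array(0, c(80, 40, 1))
  fr2[41:80, , 1] <- 1
  st2 <- new("ImageStack", frames = fr2, pixelSize = 10, frameInterval = 15,
             channel = "ros")
  stepP <- intensityProfile(st2, 1, 20, smooth = 50, normalize = TRUE)
  expect_equal(min(stepP$intensity), 0)
  expect_equal(max(stepP$intensity), 1)
  ramp <- which(stepP$intensity > 0.01 & stepP$intensity < 0.99)
  expect_lte(diff(range(stepP$distance[ramp])), 60)  # ~50 µm ramp
})

test_that("planar death vectors point along the propagation direction", {
  m1 <- matrix(FALSE, 60, 60); m1[, 1:20] <- TRUE
  m2 <- matrix(FALSE, 60, 60); m2[, 1:30] <- TRUE
  vf <- deathVectorField(m1, m2, pixelSize = 10)
  a <- angles(vf); a <- a[!is.na(a)]
  expect_gt(length(a), 10)
  expect_true(all(abs(a) < 0.2))  # +x direction
  # reversed frame order flips every vector by pi
  vfR <- deathVectorField(m2, m1, pixelSize = 10)
  aR <- angles(vfR); aR <- aR[!is.na(aR)]
  expect_true(all(abs(abs(aR) - pi) < 0.2))
})

test_that("radial expansion gives outward-pointing vectors", {
  n <- 80
  d <- sqrt(outer((1:n - 40)^2, (1:n - 40)^2, "+"))
  vf <- deathVectorField(d <= 12, d <= 20, pixelSize = 10)
  a <- angles(vf)
  idx <- which(!is.na(a), arr.ind = TRUE)
  radial <- atan2(idx[, 1] - 40, idx[, 2] - 40)
  agree <- cos(a[idx] - radial)
  expect_gt(mean(agree > 0.8), 0.9)
})

test_that("vector entropy hits its exact bounds on degenerate inputs", {
  expect_equal(vectorEntropy(rep(0.7, 500)), 0)
  centres <- seq(-pi, pi, length.out = 31)[-31] + pi / 30
  expect_equal(vectorEntropy(rep(centres, 10)), log2(30), tolerance = 1e-12)
  # rotation by a whole bin leaves the entropy unchanged
  set.seed(5)
  a <- stats::runif(300, -pi, pi)
  expect_equal(vectorEntropy(a), vectorEntropy(a + 2 * pi / 30),
               tolerance = 1e-12)
  expect_lte(vectorEntropy(a), log2(30))
  expect_warning(h <- vectorEntropy(numeric(0)), "undefined")
  expect_true(is.na(h))
})

test_that("orientation entropy is exact on constructed fibre sets", {
  expect_equal(orientationEntropy(rep(37.2, 50)), 0)
  centres <- seq(0, 180, length.out = 91)[-91] + 1
  expect_equal(orientationEntropy(rep(centres, 3)), log2(90),
               tolerance = 1e-12)
  expect_equal(orientationEntropy(c(rep(10, 25), rep(100, 25))), 1)
  # axial folding: 181 degrees is the same fibre as 1 degree
  expect_equal(orientationEntropy(c(1, 181)), 0)
  expect_error(orientationEntropy(numeric(0)), "empty")
})

test_that("palpRatio behaves as an oxidized fraction", {
  expect_equal(palpRatio(3, 3), 0.5)
  expect_equal(palpRatio(2, 0), 1)
  expect_equal(palpRatio(0, 2), 0)
  expect_warning(r <- palpRatio(0, 0), "undefined")
  expect_true(is.na(r))
  expect_error(palpRatio(-1, 2), "nonnegative")
})

test_that("initiation sites obey both detection criteria", {
  mk <- function(n, explosive = FALSE) {
    a <- seq(0, 2 * pi, length.out = n + 1)[-1]
    f1 <- data.frame(x = 500 + 18 * cos(a), y = 500 + 18 * sin(a))
    f2 <- if (explosive) {
      # ~145 later deaths on a sparse grid (no new cluster forms, but the
      # local death count grows more than 20-fold)
      g <- expand.grid(x = seq(305, 695, by = 30), y = seq(305, 695, by = 30))
      g[sqrt((g$x - 500)^2 + (g$y - 500)^2) <= 195, ]
    } else {
      data.frame(x = 500 + stats::runif(5, -80, 80),
                 y = 500 + stats::runif(5, -80, 80))
    }
    list(f1, f2)
  }
  set.seed(2)
  hit <- detectInitiationSites(mk(6))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$nDeadInitial, 6)
  expect_lt(hit$growthFactor, 20)
  # exactly five initial cells is not enough (the rule is strictly more)
  expect_equal(nrow(detectInitiationSites(mk(5))), 0)
  # explosive growth (>= 20-fold) is excluded
  expect_equal(nrow(detectInitiationSites(mk(6, explosive = TRUE))), 0)
})

test_that("planted initiation sites are recovered with few spurious calls", {
  found <- 0; planted <- 0; spurious <- 0
  for (s in 1:8) {
    set.seed(s)
    sites <- data.frame(x = stats::runif(5, 200, 1100),
                        y = stats::runif(5, 200, 1100),
                        tFrame = sample(2:6, 5, replace = TRUE))
    cf <- generateDeathCentroids(sites, nFrames = 12, seed = s + 100)
    det <- detectInitiationSites(cf)
    planted <- planted + nrow(sites)
    for (i in seq_len(nrow(sites))) {
      dd <- sqrt((det$x - sites$x[i])^2 + (det$y - sites$y[i])^2)
      if (any(dd < 60)) found <- found + 1
    }
    for (j in seq_len(nrow(det))) {
      dd <- sqrt((sites$x - det$x[j])^2 + (sites$y - det$y[j])^2)
      if (!any(dd < 60)) spurious <- spurious + 1
    }
  }
  expect_gte(found / planted, 0.95)
  expect_lte(spurious / planted, 0.05)
})

test_that("initiation statistics reject a non-Poisson alternative", {
  ev <- generateInitiationSeries(1.01, 756, 5, seed = 1)
  # constant counts: one event in every position at mid-window
  ev@events <- data.frame(position = 1:756, t = 2.5,
                          x = 600, y = 600)
  st <- initiationStatistics(ev, seed = 1)
  expect_lt(st$countTest$p, 0.01)
})

test_that("initiation statistics demand a minimal design", {
  ev <- generateInitiationSeries(1, 10, 5, seed = 1)
  expect_error(initiationStatistics(ev), "30 positions")
})
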