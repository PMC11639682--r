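# shared fixtures, built in code

defaultParams <- rosModelParams()

# movie sized so the wave traverses ~30% of the field: keeps the top-10%
# kymograph threshold between crossed and uncrossed territory
makeSpeedStack <- function(speed, noiseSd = 0, seed = 1) {
  nF <- max(20, min(80, round(1200 / (15 * speed))))
  H <- ceiling(3.5 * speed * 15 * nF / 10)
  generateWaveStack(speed, origin = c(150, 0),
                    geometry = stackGeometry(H, 31, pixelSize = 10,
                                             frameInterval = 15,
                                             nFrames = nF),
                    noiseSd = noiseSd, seed = seed)
}

# brute-force steady-state oracle: dense sign-change scan of the rate
bruteForceRoots <- function(erastin, params, step = 1e-4, rosMax = 10) {
  grid <- seq(0, rosMax, by = step)
  v <- reactionRate(grid, erastin, params)
  i <- which(diff(sign(v)) != 0)
  (grid[i] + grid[i + 1]) / 2
}

# chi-square goodness of fit of counts against Poisson(lambda), lambda known
poissonGof <- function(counts, lambda) {
  kmax <- max(counts, stats::qpois(0.9999, lambda))
  expd <- length(counts) * c(stats::dpois(0:(kmax - 1), lambda),
                             stats::ppois(kmax - 1, lambda,
                                          lower.tail = FALSE))
  obs <- c(tabulate(counts + 1, nbins = kmax),
           sum(counts >= kmax))
  # merge bins until every expected count is at least 5
  while (length(expd) > 2 && min(expd) < 5) {
    j <- which.min(expd)
    k <- if (j == length(expd)) j - 1 else j + 1
    expd[k] <- expd[k] + expd[j]; expd <- expd[-j]
    obs[k] <- obs[k] + obs[j]; obs <- obs[-j]
  }
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = length(expd) - 1, lower.tail = FALSE)
}
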