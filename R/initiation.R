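#' @include AllClasses.R AllGenerics.R
NULL

#' Detect ferroptosis initiation sites from dead-cell centroids
#'
#' An initiation site is called where (1) more than `minCells` newly dead
#' cells appear within a circle of `radius` at the site's first-death
#' frame, and (2) the local death count grows less than `maxGrowth`-fold
#' from the first to the last frame (excluding, e.g., debris misdetected as
#' an explosive cluster). Candidate centres are greedily merged so that
#' accepted sites are at least `radius` apart.
#'
#' @param centroidFrames list (one element per frame) of data.frames with
#'   columns `x`, `y` (µm): the cells that first die at each frame.
#' @param radius clustering radius (µm).
#' @param minCells a site needs strictly more than this many newly dead
#'   cells initially.
#' @param maxGrowth upper bound (exclusive) on the first-to-last-frame
#'   growth factor of the local death count.
#' @param growthRadius radius (µm) within which the growth factor counts
#'   dead cells.
#' @return data.frame with columns `x`, `y`, `tFirst`, `nDeadInitial`,
#'   `growthFactor`; zero rows when nothing qualifies.
#' @export
detectInitiationSites <- function(centroidFrames, radius = 40, minCells = 5,
                                  maxGrowth = 20, growthRadius = 200) {
  nFrames <- length(centroidFrames)
  allDead <- do.call(rbind, lapply(seq_len(nFrames), function(f) {
    df <- centroidFrames[[f]]
    if (is.null(df) || !nrow(df)) return(NULL)
    data.frame(x = df$x, y = df$y, f = f)
  }))
  out <- data.frame(x = numeric(0), y = numeric(0), tFirst = integer(0),
                    nDeadInitial = integer(0), growthFactor = numeric(0))
  if (is.null(allDead)) return(out)
  accepted <- NULL
  for (f in seq_len(nFrames)) {
    new <- centroidFrames[[f]]
    if (is.null(new) || !nrow(new)) next
    d2 <- as.matrix(stats::dist(new[, c("x", "y")]))
    nNear <- rowSums(d2 <= radius)  # includes self
    cand <- order(-nNear)
    for (i in cand) {
      if (nNear[i] <= minCells) next
      members <- which(d2[i, ] <= radius)
      cx <- mean(new$x[members]); cy <- mean(new$y[members])
      if (!is.null(accepted) &&
          any(sqrt((accepted$x - cx)^2 + (accepted$y - cy)^2) <= radius))
        next
      nearAll <- sqrt((allDead$x - cx)^2 + (allDead$y - cy)^2) <= growthRadius
      nInit <- sum(nearAll & allDead$f <= f)
      nFinal <- sum(nearAll)
      growth <- nFinal / nInit
      site <- data.frame(x = cx, y = cy, tFirst = f,
                         nDeadInitial = length(members),
                         growthFactor = growth)
      accepted <- rbind(accepted, site)
      if (growth < maxGrowth) out <- rbind(out, site)
    }
  }
  rownames(out) <- NULL
  out
}

#' Poisson and geometric statistics of spontaneous initiations
#'
#' Tests whether spontaneous-initiation events behave like a homogeneous
#' Poisson process, the statistical signature of independent stochastic
#' initiations. Two two-sample Kolmogorov-Smirnov comparisons are made
#' against large seeded Monte-Carlo samples from the reference
#' distributions with the observed means:
#' \itemize{
#'   \item counts: events per position versus `Poisson(mean count)`;
#'   \item intervals: the per-position time series are concatenated in a
#'     random order into one long record; inter-event intervals on the
#'     acquisition clock are compared against a geometric distribution with
#'     the observed mean interval.
#' }
#'
#' @param series an [EventSeries-class]; needs at least 30 positions.
#' @param nMC Monte-Carlo reference sample size.
#' @param seed integer seed for the Monte-Carlo samples and the random
#'   concatenation order.
#' @return List with elements `countTest` (`p`, `statistic`, `meanCount`,
#'   `n`) and `intervalTest` (`p`, `statistic`, `meanIntervalH`, `n`);
#'   `intervalTest` entries are `NA` with fewer than 2 events.
#' @export
initiationStatistics <- function(series, nMC = 1e5, seed = 1) {
  stopifnot(is(series, "EventSeries"))
  if (series@nPositions < 30) stop("need at least 30 positions")
  if (!is.null(seed)) set.seed(seed)
  ev <- eventTable(series)
  counts <- tabulate(ev$position, nbins = series@nPositions)
  lambda <- mean(counts)
  mcCounts <- stats::rpois(nMC, lambda)
  ct <- suppressWarnings(stats::ks.test(counts, mcCounts))
  countTest <- list(p = ct$p.value, statistic = unname(ct$statistic),
                    meanCount = lambda, n = length(counts))
  if (nrow(ev) < 2) {
    intervalTest <- list(p = NA_real_, statistic = NA_real_,
                         meanIntervalH = NA_real_, n = 0L)
  } else {
    ord <- sample.int(series@nPositions)
    offset <- stats::setNames(series@window * (seq_along(ord) - 1), ord)
    tt <- ev$t + offset[as.character(ev$position)]
    tt <- sort(tt)
    ticks <- round(diff(tt) / series@clockRes)
    meanTicks <- mean(ticks)
    p <- 1 / (1 + meanTicks)
    mcTicks <- stats::rgeom(nMC, p)
    it <- suppressWarnings(stats::ks.test(ticks, mcTicks))
    intervalTest <- list(p = it$p.value, statistic = unname(it$statistic),
                         meanIntervalH = meanTicks * series@clockRes,
                         n = length(ticks))
  }
  list(countTest = countTest, intervalTest = intervalTest)
}
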