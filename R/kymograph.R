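#' @include AllClasses.R AllGenerics.R
NULL

#' Build a kymograph along a propagation axis
#'
#' For each position along the axis and each frame, the kymograph value is
#' the maximum signal over a transverse band of the given width. The axis
#' runs along rows by default (`direction = "row"`: positions are rows, the
#' band spans columns around `axisIndex`); `direction = "col"` transposes
#' the convention.
#'
#' @param stack an [ImageStack-class].
#' @param axisIndex column (for `direction = "row"`) or row (for
#'   `direction = "col"`) the axis passes through, in pixels.
#' @param width transverse width (µm); clipped with a warning when it
#'   exceeds the image.
#' @param direction `"row"` or `"col"`, the image axis the wave propagates
#'   along.
#' @param denoise side (pixels, odd; 1 disables) of a box filter applied to
#'   each frame before the max projection. The maximum over the transverse
#'   band is an extreme statistic that inflates pixel noise; light spatial
#'   averaging first keeps the projection representative of the signal.
#' @return A [Kymograph-class] (space x time).
#' @examples
#' st <- generateWaveStack(5.5, seed = 1)
#' k <- buildKymograph(st$death, axisIndex = 1)
#' estimateWaveSpeed(k)
#' @export
buildKymograph <- function(stack, axisIndex, width = 250,
                           direction = c("row", "col"), denoise = 3) {
  stopifnot(is(stack, "ImageStack"))
  direction <- match.arg(direction)
  fr <- frames(stack)
  if (direction == "col") fr <- aperm(fr, c(2, 1, 3))
  if (denoise > 1) {
    kern <- matrix(1 / denoise^2, denoise, denoise)
    for (k in seq_len(dim(fr)[3]))
      fr[, , k] <- EBImage::imageData(
        EBImage::filter2(EBImage::Image(fr[, , k]), kern,
                         boundary = "replicate"))
  }
  px <- pixelSize(stack)
  if (axisIndex < 1 || axisIndex > dim(fr)[2]) stop("axis outside image")
  half <- floor(width / (2 * px))
  lo <- axisIndex - half
  hi <- axisIndex + half
  if (lo < 1 || hi > dim(fr)[2]) {
    warning("width exceeds image: clipping the transverse band")
    lo <- max(1, lo); hi <- min(dim(fr)[2], hi)
  }
  nT <- dim(fr)[3]
  m <- vapply(seq_len(nT), function(k) {
    band <- fr[, lo:hi, k, drop = FALSE]
    apply(band, 1, max)
  }, numeric(dim(fr)[1]))
  new("Kymograph", matrix = m, dy = px, dt = frameInterval(stack),
      widthUsed = (hi - lo + 1) * px)
}

#' Estimate wave speed from a kymograph
#'
#' The kymograph is thresholded at its top `100 - intensityPct` percent of
#' intensity (default top 10%). For each spatial position the earliest frame
#' reaching the threshold is marked; per frame, the positions first crossing
#' at that frame form a distribution whose mode (1-pixel histogram, ties
#' broken toward the smaller coordinate) anchors the front, and the
#' `nLocations` positions closest to the mode enter a linear least-squares
#' fit of position against time, whose slope is the wave speed.
#'
#' @param kymo a [Kymograph-class].
#' @param intensityPct percentile of kymograph intensity defining the
#'   threshold (90 keeps the top 10%).
#' @param nLocations positions per frame entering the fit.
#' @param frameRange optional integer length-2, restricting the fit to a
#'   window of frames (useful around a speed change-point).
#' @param minFrames minimum number of frames with crossings required.
#' @return A [SpeedEstimate-class]; status `"no-wave"` when fewer than
#'   `minFrames` frames have threshold crossings.
#' @export
estimateWaveSpeed <- function(kymo, intensityPct = 90, nLocations = 11,
                              frameRange = NULL, minFrames = 3) {
  stopifnot(is(kymo, "Kymograph"))
  m <- kymo@matrix
  thr <- stats::quantile(m, intensityPct / 100, names = FALSE)
  # tolerate float jitter on plateaus (e.g. filter round-off): a value equal
  # to the threshold up to rounding counts as crossed
  thr <- thr - 1e-8 * diff(range(m))
  nPos <- nrow(m)
  nT <- ncol(m)
  firstT <- rep(NA_integer_, nPos)
  for (y in seq_len(nPos)) {
    w <- which(m[y, ] >= thr)
    if (length(w)) firstT[y] <- w[1]
  }
  framesIdx <- seq_len(nT)
  if (!is.null(frameRange))
    framesIdx <- framesIdx[framesIdx >= frameRange[1] &
                             framesIdx <= frameRange[2]]
  pts <- NULL
  for (tt in framesIdx) {
    ys <- which(firstT == tt)
    if (!length(ys)) next
    counts <- tabulate(ys, nbins = nPos)
    mode <- which.max(counts)  # ties resolve to the smaller coordinate
    sel <- ys[order(abs(ys - mode), ys)][seq_len(min(nLocations, length(ys)))]
    pts <- rbind(pts, data.frame(t = (tt - 1) * kymo@dt,
                                 y = (sel - 1) * kymo@dy))
  }
  noWave <- new("SpeedEstimate", speed = NA_real_, stderr = NA_real_,
                r2 = NA_real_,
                fitPoints = data.frame(t = numeric(0), y = numeric(0)),
                status = "no-wave")
  if (is.null(pts) || length(unique(pts$t)) < minFrames) return(noWave)
  fit <- stats::lm(y ~ t, data = pts)
  s <- suppressWarnings(summary(fit))  # noiseless kymographs fit exactly
  new("SpeedEstimate", speed = unname(stats::coef(fit)[2]),
      stderr = s$coefficients[2, 2], r2 = s$r.squared,
      fitPoints = pts, status = "ok")
}
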