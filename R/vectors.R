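#' @include AllClasses.R AllGenerics.R
NULL

# central-difference gradient; x along columns, y along rows (edge: one-sided)
.gradient <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gx <- matrix(0, nr, nc)
  gy <- matrix(0, nr, nc)
  if (nc >= 3) gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  if (nc >= 2) {
    gx[, 1] <- m[, 2] - m[, 1]
    gx[, nc] <- m[, nc] - m[, nc - 1]
  }
  if (nr >= 3) gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  if (nr >= 2) {
    gy[1, ] <- m[2, ] - m[1, ]
    gy[nr, ] <- m[nr, ] - m[nr - 1, ]
  }
  list(x = gx, y = gy)
}

#' Cell-death progression vectors between two consecutive outlines
#'
#' Builds a vector field describing the local direction of death
#' progression from the death regions at two consecutive timepoints. Both
#' masks are Gaussian-smoothed (sigma in pixels); the direction at each
#' location is down the gradient of the combined death occupancy (pointing
#' from already-dead towards not-yet-dead territory), signed by the net
#' growth between the two frames, and the magnitude is the absolute
#' smoothed frame difference. Reversing the frame order flips every vector
#' by pi.
#'
#' @param outline1,outline2 logical death masks at t and t+1 (nonempty).
#' @param pixelSize µm per pixel.
#' @param sigma Gaussian smoothing sigma (pixels).
#' @param magTol fraction of the maximal magnitude below which no angle is
#'   reported.
#' @return A [DeathVectorField-class].
#' @export
deathVectorField <- function(outline1, outline2, pixelSize = 1, sigma = 2,
                             magTol = 1e-3) {
  if (!any(outline1) || !any(outline2))
    stop("both outlines must be nonempty")
  stopifnot(identical(dim(outline1), dim(outline2)))
  sm <- function(m)
    EBImage::imageData(EBImage::gblur(EBImage::Image(m * 1), sigma = sigma))
  occupancy <- sm((outline1 + outline2) / 2)
  diffMag <- abs(sm(outline2 * 1 - outline1 * 1))
  g <- .gradient(occupancy)
  # down the occupancy gradient = direction of advance; flip when the death
  # area shrank (frames given in reverse order)
  sgn <- if (sum(outline2) >= sum(outline1)) 1 else -1
  vx <- -sgn * g$x
  vy <- -sgn * g$y
  gradMag <- sqrt(vx^2 + vy^2)
  mag <- diffMag * (gradMag > 0)
  ang <- atan2(vy, vx)
  ang[mag < magTol * max(mag, .Machine$double.eps)] <- NA_real_
  new("DeathVectorField", angle = ang, magnitude = mag,
      pixelSize = pixelSize)
}

# Shannon entropy (bits) of a histogram of angular data
.binEntropy <- function(values, breaks) {
  counts <- graphics::hist(values, breaks = breaks, plot = FALSE)$counts
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Angular entropy of a death vector field
#'
#' Shannon entropy (bits) of the histogram of vector angles over `nBins`
#' equal bins spanning the full circle. Zero for perfectly aligned vectors;
#' at most `log2(nBins)` (about 4.9069 bits for 30 bins) for a uniform
#' angle distribution. Ordered trigger-wave propagation gives low entropy,
#' spatially random death gives high entropy.
#'
#' @param vf a [DeathVectorField-class], or a numeric vector of angles
#'   (radians).
#' @param region optional logical mask selecting the neighbourhood to
#'   evaluate (e.g. a window of 100 x 350 µm around an initiation site).
#' @param nBins number of angular bins over 360°.
#' @return Entropy in bits; `NA` (with a warning) when the selection holds
#'   no vectors.
#' @examples
#' vectorEntropy(rep(0.3, 100))        # 0 bits
#' log2(30)                            # upper bound for the default bins
#' @export
vectorEntropy <- function(vf, region = NULL, nBins = 30) {
  a <- if (is(vf, "DeathVectorField")) angles(vf) else as.numeric(vf)
  if (!is.null(region)) {
    stopifnot(identical(dim(region), dim(a)))
    a <- a[region]
  }
  a <- a[!is.na(a)]
  if (!length(a)) {
    warning("no vectors in selection: entropy undefined")
    return(NA_real_)
  }
  # map angles into (-pi, pi] then bin the full circle
  a <- ((a + pi) %% (2 * pi)) - pi
  breaks <- seq(-pi, pi, length.out = nBins + 1)
  a[a <= -pi] <- -pi + 1e-12
  .binEntropy(a, breaks)
}

#' Entropy of fibre orientations
#'
#' Shannon entropy (bits) of a histogram of fibre orientations over `nBins`
#' equal bins spanning 0-180° (orientations are axial and are folded into
#' that range). Bounded by `log2(nBins)` (about 6.4919 bits for 90 bins).
#'
#' @param orientations numeric vector of orientations in degrees.
#' @param nBins number of bins over 0-180°.
#' @return Entropy in bits.
#' @export
orientationEntropy <- function(orientations, nBins = 90) {
  if (!length(orientations)) stop("empty orientation list")
  o <- orientations %% 180
  breaks <- seq(0, 180, length.out = nBins + 1)
  .binEntropy(o, breaks)
}

#' Lipid-peroxidation ratio
#'
#' Fraction of oxidized probe signal: `oxidized / (oxidized + reduced)`,
#' the standard readout of ratiometric lipid-peroxidation probes
#' (e.g. C11-BODIPY 581/591).
#'
#' @param oxidized,reduced nonnegative intensities (vectorized).
#' @return Ratio in `[0, 1]`; `NA` where both intensities are zero.
#' @export
palpRatio <- function(oxidized, reduced) {
  if (any(oxidized < 0) || any(reduced < 0))
    stop("intensities must be nonnegative")
  tot <- oxidized + reduced
  out <- ifelse(tot == 0, NA_real_, oxidized / tot)
  if (any(is.na(out))) warning("both intensities zero: ratio undefined")
  out
}
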