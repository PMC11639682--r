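#' @include AllClasses.R AllGenerics.R
NULL

# top-fraction binarization -> dilation -> mean filter -> re-binarize at 0.5
.outlineFromImage <- function(img, topFrac, dilateRadius, filterSize) {
  rng <- range(img)
  if (diff(rng) == 0) {
    warning("flat image: no top-intensity tail, returning empty mask")
    return(matrix(FALSE, nrow(img), ncol(img)))
  }
  thr <- stats::quantile(img, 1 - topFrac, names = FALSE)
  mask <- img >= thr
  m <- EBImage::Image(mask * 1)
  if (dilateRadius > 0)
    m <- EBImage::dilate(m, EBImage::makeBrush(2 * dilateRadius + 1, "disc"))
  if (filterSize > 1) {
    kern <- matrix(1 / filterSize^2, filterSize, filterSize)
    m <- EBImage::filter2(m, kern)
  }
  EBImage::imageData(m) >= 0.5
}

#' Wave outline of one frame
#'
#' Binary mask of the wave-propagation boundary: the top `topFrac` of the
#' frame's intensities is binarized, dilated with a disc, mean-filtered and
#' re-binarized at 0.5. A flat frame yields an empty mask with a warning.
#'
#' @param stack an [ImageStack-class].
#' @param frame frame index (1-based).
#' @param topFrac intensity fraction kept by the threshold (default top 1%).
#' @param dilateRadius dilation radius in pixels.
#' @param filterSize mean-filter side in pixels.
#' @return Logical H x W matrix.
#' @export
waveOutline <- function(stack, frame, topFrac = 0.01, dilateRadius = 3,
                        filterSize = 5) {
  stopifnot(is(stack, "ImageStack"))
  if (frame < 1 || frame > nFrames(stack)) stop("frame out of range")
  .outlineFromImage(frames(stack)[, , frame], topFrac, dilateRadius,
                    filterSize)
}

#' Wavefront mask from a frame-to-frame intensity increase
#'
#' For signals whose wavefront is a rising band (ROS, lipid peroxidation),
#' the front is the increase between two consecutive frames: the outline is
#' computed on the positive part of the difference image, then small
#' components (debris) are removed by a size filter.
#'
#' @param stack an [ImageStack-class].
#' @param frame frame index, must be >= 2 (the difference is to
#'   `frame - 1`).
#' @param minObjectArea smallest connected-component area kept (µm²).
#' @param topFrac,dilateRadius,filterSize passed to the outline step.
#' @return Logical H x W matrix.
#' @export
frontIncrement <- function(stack, frame, minObjectArea = 40, topFrac = 0.01,
                           dilateRadius = 3, filterSize = 5) {
  stopifnot(is(stack, "ImageStack"))
  if (frame < 2) stop("frame must be >= 2: the increment needs a predecessor")
  if (frame > nFrames(stack)) stop("frame out of range")
  d <- pmax(frames(stack)[, , frame] - frames(stack)[, , frame - 1], 0)
  if (all(d == 0)) return(matrix(FALSE, dim(d)[1], dim(d)[2]))
  mask <- .outlineFromImage(d, topFrac, dilateRadius, filterSize)
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- table(lab[lab > 0]) * pixelSize(stack)^2
  keep <- as.integer(names(areas)[areas >= minObjectArea])
  matrix(as.vector(lab) %in% keep, nrow(mask), ncol(mask))
}

#' Transverse-mean intensity profile along the propagation axis
#'
#' Mean intensity per position along the axis, averaged over a transverse
#' width, then smoothed with a moving average; optionally min-max
#' normalized (a constant profile maps to all zeros by convention).
#'
#' @param stack an [ImageStack-class].
#' @param frame frame index.
#' @param axisCol column index (pixels) of the axis; the profile runs along
#'   rows.
#' @param width transverse width averaged over (µm); clipped to the image
#'   with a warning if too wide.
#' @param smooth moving-average window (µm).
#' @param normalize min-max normalize the smoothed profile.
#' @return data.frame with columns `distance` (µm along the axis) and
#'   `intensity`.
#' @export
intensityProfile <- function(stack, frame, axisCol, width = 250, smooth = 50,
                             normalize = FALSE) {
  stopifnot(is(stack, "ImageStack"))
  if (frame < 1 || frame > nFrames(stack)) stop("frame out of range")
  img <- frames(stack)[, , frame]
  px <- pixelSize(stack)
  if (axisCol < 1 || axisCol > ncol(img)) stop("axisCol outside image")
  half <- floor(width / (2 * px))
  lo <- axisCol - half
  hi <- axisCol + half
  if (lo < 1 || hi > ncol(img)) {
    warning("width exceeds image: clipping the transverse band")
    lo <- max(1, lo); hi <- min(ncol(img), hi)
  }
  prof <- rowMeans(img[, lo:hi, drop = FALSE])
  w <- max(1, round(smooth / px))
  if (w %% 2 == 0) w <- w + 1
  if (w > 1) {
    kern <- rep(1 / w, w)
    # moving average with edge replication
    padded <- c(rep(prof[1], w %/% 2), prof, rep(prof[length(prof)], w %/% 2))
    prof <- stats::filter(padded, kern, sides = 2)
    prof <- as.numeric(prof[(w %/% 2 + 1):(w %/% 2 + length(img[, 1]))])
  }
  if (normalize) {
    rng <- range(prof)
    prof <- if (diff(rng) == 0) rep(0, length(prof))
            else (prof - rng[1]) / diff(rng)
  }
  data.frame(distance = (seq_along(prof) - 1) * px, intensity = prof)
}

# radius at which a mask is crossed along a ray from `origin` at `angle`:
# the farthest mask pixel within half a pixel of the ray
.rayCrossing <- function(mask, origin, angle, px) {
  maxR <- sqrt((nrow(mask) * px)^2 + (ncol(mask) * px)^2)
  rs <- seq(0, maxR, by = px / 2)
  xs <- origin[1] + rs * cos(angle)
  ys <- origin[2] + rs * sin(angle)
  ci <- round(xs / px) + 1
  ri <- round(ys / px) + 1
  ok <- ri >= 1 & ri <= nrow(mask) & ci >= 1 & ci <= ncol(mask)
  if (!any(ok)) return(NA_real_)
  hit <- mask[cbind(ri[ok], ci[ok])]
  if (!any(hit)) return(NA_real_)
  max(rs[ok][hit])
}

#' Wavefront width and amplitude between two consecutive outlines
#'
#' Casts rays from the wave origin in `nDirections` directions; for each
#' ray, the width is the distance between the crossing radii of the two
#' outlines and the amplitude is the maximal ROS intensity between them.
#' Directions whose ray misses either outline are skipped.
#'
#' @param outline1,outline2 logical masks of consecutive outlines
#'   (earlier, later).
#' @param rosFrame numeric matrix of ROS intensities (same size).
#' @param origin wave origin (µm, x then y).
#' @param pixelSize µm per pixel.
#' @param nDirections number of equally spaced rays.
#' @return List with `perDirection` (data.frame: angle, width, amplitude),
#'   and the means `width` and `amplitude` over the usable directions.
#' @export
frontWidthAmplitude <- function(outline1, outline2, rosFrame, origin,
                                pixelSize, nDirections = 12) {
  stopifnot(any(outline1), any(outline2),
            identical(dim(outline1), dim(outline2)),
            identical(dim(outline1), dim(rosFrame)))
  angles <- 2 * pi * (seq_len(nDirections) - 1) / nDirections
  rows <- NULL
  for (a in angles) {
    r1 <- .rayCrossing(outline1, origin, a, pixelSize)
    r2 <- .rayCrossing(outline2, origin, a, pixelSize)
    if (is.na(r1) || is.na(r2) || r2 <= r1) next
    rs <- seq(r1, r2, by = pixelSize / 2)
    ci <- round((origin[1] + rs * cos(a)) / pixelSize) + 1
    ri <- round((origin[2] + rs * sin(a)) / pixelSize) + 1
    ok <- ri >= 1 & ri <= nrow(rosFrame) & ci >= 1 & ci <= ncol(rosFrame)
    if (!any(ok)) next
    amp <- max(rosFrame[cbind(ri[ok], ci[ok])])
    rows <- rbind(rows, data.frame(angle = a, width = r2 - r1,
                                   amplitude = amp))
  }
  if (is.null(rows))
    rows <- data.frame(angle = numeric(0), width = numeric(0),
                       amplitude = numeric(0))
  list(perDirection = rows,
       width = if (nrow(rows)) mean(rows$width) else NA_real_,
       amplitude = if (nrow(rows)) mean(rows$amplitude) else NA_real_)
}
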