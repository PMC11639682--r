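#' @include AllClasses.R AllGenerics.R
NULL

#' Stack geometry descriptor
#'
#' Convenience constructor for the geometry argument of the image
#' generators. The default mirrors a single imaging position of
#' 1.26 x 1.26 mm².
#'
#' @param height,width image size in pixels.
#' @param pixelSize µm per pixel.
#' @param frameInterval min between frames.
#' @param nFrames number of frames.
#' @return A named list.
#' @export
stackGeometry <- function(height = 126, width = 126, pixelSize = 10,
                          frameInterval = 15, nFrames = 40) {
  stopifnot(height >= 1, width >= 1, pixelSize > 0, frameInterval > 0,
            nFrames >= 1)
  list(height = as.integer(height), width = as.integer(width),
       pixelSize = pixelSize, frameInterval = frameInterval,
       nFrames = as.integer(nFrames))
}

# pixel-centre coordinate grids (µm), 0-based
.pixelCoords <- function(geom) {
  list(x = matrix(rep((seq_len(geom$width) - 1) * geom$pixelSize,
                      each = geom$height), nrow = geom$height),
       y = matrix(rep((seq_len(geom$height) - 1) * geom$pixelSize,
                      times = geom$width), nrow = geom$height))
}

#' Generate a synthetic trigger-wave image stack
#'
#' Emulates the phenomenology of a propagating ferroptotic wave in
#' time-lapse microscopy: the cell-death (nuclear dye) channel steps from a
#' low to a high intensity when the death front passes a pixel, and the ROS
#' channel is a Gaussian band of elevated signal leading the death front by
#' `lag` minutes. The front is radial from `origin` by default, or planar
#' (moving along increasing row coordinate, position measured as the row
#' distance from `origin[2]`).
#'
#' The death channel is a binary step plus noise rather than textured
#' nuclei: the downstream quantifications operate on intensity thresholds,
#' not on cell morphology.
#'
#' @param speed front speed (µm/min), > 0.
#' @param origin numeric length-2, front origin in µm (x, y).
#' @param t0 time at which the front leaves the origin (min).
#' @param geometry a [stackGeometry()] list.
#' @param front `"radial"` or `"planar"`.
#' @param deathBase,deathRise baseline intensity and step height of the
#'   death channel.
#' @param rosBase,rosAmp baseline and peak amplitude of the ROS band.
#' @param rosFrontWidth Gaussian sigma of the ROS band (µm).
#' @param lag time by which the ROS front leads the death front (min);
#'   the ROS band therefore leads by `lag * speed` µm.
#' @param noiseSd additive Gaussian noise s.d. (intensity units).
#' @param seed integer seed; identical seeds give identical stacks.
#' @return Named list with [ImageStack-class] elements `death` and `ros`,
#'   carrying a `truth` attribute with the generating parameters.
#' @examples
#' st <- generateWaveStack(5.5, seed = 1)
#' st$death
#' @export
generateWaveStack <- function(speed, origin = c(0, 0), t0 = 0,
                              geometry = stackGeometry(),
                              front = c("radial", "planar"),
                              deathBase = 0.1, deathRise = 1,
                              rosBase = 0.1, rosAmp = 1,
                              rosFrontWidth = 50, lag = 60,
                              noiseSd = 0, seed = NULL) {
  front <- match.arg(front)
  stopifnot(speed > 0, rosFrontWidth > 0, noiseSd >= 0)
  if (!is.null(seed)) set.seed(seed)
  g <- geometry
  co <- .pixelCoords(g)
  dist <- if (front == "radial")
    sqrt((co$x - origin[1])^2 + (co$y - origin[2])^2)
  else
    co$y - origin[2]
  times <- (seq_len(g$nFrames) - 1) * g$frameInterval
  death <- array(0, c(g$height, g$width, g$nFrames))
  ros <- array(0, c(g$height, g$width, g$nFrames))
  for (k in seq_len(g$nFrames)) {
    rDeath <- speed * (times[k] - t0)
    rRos <- speed * (times[k] - t0 + lag)
    death[, , k] <- deathBase + deathRise * (dist <= rDeath)
    ros[, , k] <- rosBase +
      rosAmp * exp(-(dist - rRos)^2 / (2 * rosFrontWidth^2))
  }
  if (noiseSd > 0) {
    death <- death + stats::rnorm(length(death), sd = noiseSd)
    ros <- ros + stats::rnorm(length(ros), sd = noiseSd)
  }
  death <- pmax(death, 0)
  ros <- pmax(ros, 0)
  maxDist <- max(dist)
  if (g$nFrames >= 3 && speed * (times[3] - t0) > maxDist)
    warning("front exits the field before 3 frames")
  truth <- list(speed = speed, origin = origin, t0 = t0, front = front,
                lag = lag, deathBase = deathBase, deathRise = deathRise,
                rosFrontWidth = rosFrontWidth, noiseSd = noiseSd, seed = seed)
  out <- list(
    death = new("ImageStack", frames = death, pixelSize = g$pixelSize,
                frameInterval = g$frameInterval, channel = "death"),
    ros = new("ImageStack", frames = ros, pixelSize = g$pixelSize,
              frameInterval = g$frameInterval, channel = "ros")
  )
  attr(out, "truth") <- truth
  out
}

#' Generate a spatially random cell-death stack
#'
#' Null counterpart of [generateWaveStack()]: small death foci appear at
#' uniformly random positions and times and persist, with no spatial order.
#' Used to contrast ordered wave propagation against spatially uncoordinated
#' death in the vector-entropy analysis.
#'
#' @param geometry a [stackGeometry()] list.
#' @param nFoci total number of death foci over the movie.
#' @param focusRadius radius of each focus (µm).
#' @param deathBase,deathRise baseline and step height.
#' @param noiseSd additive Gaussian noise s.d.
#' @param seed integer seed.
#' @return An [ImageStack-class] (death channel).
#' @export
generateRandomDeathStack <- function(geometry = stackGeometry(), nFoci = 150,
                                     focusRadius = 30, deathBase = 0.1,
                                     deathRise = 1, noiseSd = 0,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- geometry
  co <- .pixelCoords(g)
  fx <- stats::runif(nFoci, 0, (g$width - 1) * g$pixelSize)
  fy <- stats::runif(nFoci, 0, (g$height - 1) * g$pixelSize)
  ft <- sample.int(g$nFrames, nFoci, replace = TRUE)
  dead <- matrix(FALSE, g$height, g$width)
  frames <- array(0, c(g$height, g$width, g$nFrames))
  for (k in seq_len(g$nFrames)) {
    idx <- which(ft == k)
    for (i in idx)
      dead <- dead | (sqrt((co$x - fx[i])^2 + (co$y - fy[i])^2) <= focusRadius)
    frames[, , k] <- deathBase + deathRise * dead
  }
  if (noiseSd > 0)
    frames <- pmax(frames + stats::rnorm(length(frames), sd = noiseSd), 0)
  new("ImageStack", frames = frames, pixelSize = g$pixelSize,
      frameInterval = g$frameInterval, channel = "death")
}

#' Generate spontaneous initiation events
#'
#' Per-position event counts are Poisson with the given rate per window;
#' event times are uniform on a discrete acquisition clock within the
#' window (so pooled inter-event intervals on that clock are geometric).
#' Event sites are uniform within each position's field.
#'
#' @param rate expected events per position per window.
#' @param nPositions number of imaging positions.
#' @param window observation window (h).
#' @param fieldSize side of each position's square field (µm).
#' @param clockRes acquisition clock resolution (h); event times are
#'   multiples of this.
#' @param seed integer seed.
#' @return An [EventSeries-class].
#' @examples
#' ev <- generateInitiationSeries(1.01, nPositions = 756, window = 5, seed = 1)
#' mean(tabulate(eventTable(ev)$position, 756))
#' @export
generateInitiationSeries <- function(rate, nPositions = 756, window = 5,
                                     fieldSize = 1260, clockRes = 1 / 6,
                                     seed = NULL) {
  stopifnot(rate > 0, nPositions >= 1, window > 0, clockRes > 0)
  if (!is.null(seed)) set.seed(seed)
  counts <- stats::rpois(nPositions, rate)
  n <- sum(counts)
  pos <- rep(seq_len(nPositions), counts)
  nTicks <- max(1L, round(window / clockRes))
  t <- clockRes * (sample.int(nTicks, n, replace = TRUE) - 1L)
  ev <- data.frame(position = pos, t = t,
                   x = stats::runif(n, 0, fieldSize),
                   y = stats::runif(n, 0, fieldSize))
  ev <- ev[order(ev$position, ev$t), , drop = FALSE]
  rownames(ev) <- NULL
  new("EventSeries", events = ev, window = window,
      nPositions = nPositions, clockRes = clockRes)
}

#' Dose-response model functions
#'
#' The three parametric forms fitted to trigger-wave speed versus drug
#' concentration: Michaelian inhibition
#' \eqn{y = y_0 + (y_M - y_0) K/(K + x)}, Michaelian activation
#' \eqn{y = y_0 + (y_M - y_0) x/(K + x)}, and biphasic inhibition
#' \eqn{y = y_0 + y_M (1 - f_1 x/(K_1+x) - (1-f_1) x/(K_2+x))}.
#'
#' @param x dose(s), same units as `K`.
#' @param y0,yM,K,f1,K1,K2 model parameters.
#' @return Predicted speed(s).
#' @name doseModels
NULL

#' @rdname doseModels
#' @export
michaelianInhibition <- function(x, y0, yM, K) y0 + (yM - y0) * K / (K + x)

#' @rdname doseModels
#' @export
michaelianActivation <- function(x, y0, yM, K) y0 + (yM - y0) * x / (K + x)

#' @rdname doseModels
#' @export
biphasicInhibition <- function(x, y0, yM, f1, K1, K2)
  y0 + yM * (1 - f1 * x / (K1 + x) - (1 - f1) * x / (K2 + x))

#' Generate synthetic dose-response data
#'
#' Evaluates one of the [doseModels] at the given doses and adds seeded
#' Gaussian noise.
#'
#' @param model `"michaelian_inh"`, `"michaelian_act"` or `"biphasic"`.
#' @param trueParams named list/vector of the model's parameters.
#' @param doses nonnegative dose vector.
#' @param noiseSd Gaussian noise s.d. (speed units).
#' @param seed integer seed.
#' @return data.frame with columns `dose`, `speed`.
#' @export
generateDoseResponse <- function(model = c("michaelian_inh", "michaelian_act",
                                           "biphasic"),
                                 trueParams, doses, noiseSd = 0,
                                 seed = NULL) {
  model <- match.arg(model)
  stopifnot(all(doses >= 0), noiseSd >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(trueParams)
  y <- switch(model,
    michaelian_inh = michaelianInhibition(doses, p$y0, p$yM, p$K),
    michaelian_act = michaelianActivation(doses, p$y0, p$yM, p$K),
    biphasic = biphasicInhibition(doses, p$y0, p$yM, p$f1, p$K1, p$K2))
  if (noiseSd > 0) y <- y + stats::rnorm(length(doses), sd = noiseSd)
  data.frame(dose = doses, speed = y)
}

#' Generate per-frame dead-cell centroids with planted initiation sites
#'
#' Builds the input of [detectInitiationSites()]: for each planted site, a
#' tight cluster of newly dead cells appears at the site's first frame, and
#' the cluster gains cells in later frames (modest growth). Optional
#' scattered background deaths emulate isolated single-cell events that
#' should not be called sites.
#'
#' @param sites data.frame with columns `x`, `y` (µm) and `tFrame`
#'   (first-death frame, 1-based).
#' @param nFrames number of frames.
#' @param cellsPerSite newly dead cells forming each site initially
#'   (must exceed the detector's `minCells` to be recoverable).
#' @param clusterRadius radius within which the initial cells scatter (µm).
#' @param growthPerFrame newly dead cells added near each site per later
#'   frame.
#' @param backgroundPerFrame isolated background deaths per frame.
#' @param fieldSize field side (µm).
#' @param seed integer seed.
#' @return List (length `nFrames`) of data.frames with columns `x`, `y`:
#'   the cells that first die at each frame.
#' @export
generateDeathCentroids <- function(sites, nFrames, cellsPerSite = 8,
                                   clusterRadius = 25, growthPerFrame = 3,
                                   backgroundPerFrame = 1, fieldSize = 1260,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frames <- replicate(nFrames, data.frame(x = numeric(0), y = numeric(0)),
                      simplify = FALSE)
  addCells <- function(f, x, y) {
    frames[[f]] <<- rbind(frames[[f]], data.frame(x = x, y = y))
  }
  for (i in seq_len(nrow(sites))) {
    f0 <- sites$tFrame[i]
    a <- stats::runif(cellsPerSite, 0, 2 * pi)
    r <- clusterRadius * sqrt(stats::runif(cellsPerSite))
    addCells(f0, sites$x[i] + r * cos(a), sites$y[i] + r * sin(a))
    if (f0 < nFrames && growthPerFrame > 0) {
      for (f in (f0 + 1):nFrames) {
        grow <- 2 * clusterRadius + clusterRadius * (f - f0)
        a <- stats::runif(growthPerFrame, 0, 2 * pi)
        r <- grow * sqrt(stats::runif(growthPerFrame))
        addCells(f, sites$x[i] + r * cos(a), sites$y[i] + r * sin(a))
      }
    }
  }
  if (backgroundPerFrame > 0) {
    for (f in seq_len(nFrames))
      addCells(f, stats::runif(backgroundPerFrame, 0, fieldSize),
               stats::runif(backgroundPerFrame, 0, fieldSize))
  }
  frames
}

#' Write / read an image stack as multi-frame TIFF with a YAML sidecar
#'
#' The stack is written as a 32-bit float multi-frame TIFF; the physical
#' calibration (`pixel_size_um`, `frame_interval_min`, `channel`) goes to a
#' YAML sidecar at `<path>.yaml`.
#'
#' @param stack an [ImageStack-class].
#' @param path TIFF file path.
#' @return `writeImageStack` returns `path` invisibly; `readImageStack`
#'   returns an [ImageStack-class].
#' @export
writeImageStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  fr <- frames(stack)
  # TIFF sample values are defined on [0, 1]; rescale and record the factor
  sc <- max(fr, 1)
  lst <- lapply(seq_len(dim(fr)[3]), function(k) fr[, , k] / sc)
  tiff::writeTIFF(lst, path, bits.per.sample = 32L)
  yaml::write_yaml(list(pixel_size_um = pixelSize(stack),
                        frame_interval_min = frameInterval(stack),
                        channel = channelName(stack),
                        intensity_scale = sc),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
  lst <- tiff::readTIFF(path, all = TRUE)
  meta <- yaml::yaml.load_file(paste0(path, ".yaml"))
  sc <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  fr <- array(0, c(dim(lst[[1]])[1], dim(lst[[1]])[2], length(lst)))
  for (k in seq_along(lst)) fr[, , k] <- lst[[k]] * sc
  new("ImageStack", frames = fr, pixelSize = meta$pixel_size_um,
      frameInterval = meta$frame_interval_min, channel = meta$channel)
}

#' Write / read an event series as CSV with a YAML sidecar
#'
#' @param series an [EventSeries-class].
#' @param path CSV file path (columns `position_id`, `t_h`, `x_um`, `y_um`);
#'   window/positions/clock metadata goes to `<path>.yaml`.
#' @return `writeEventSeries` returns `path` invisibly; `readEventSeries`
#'   returns an [EventSeries-class].
#' @export
writeEventSeries <- function(series, path) {
  stopifnot(is(series, "EventSeries"))
  ev <- eventTable(series)
  utils::write.csv(data.frame(position_id = ev$position, t_h = ev$t,
                              x_um = ev$x, y_um = ev$y),
                   path, row.names = FALSE)
  yaml::write_yaml(list(window_h = series@window,
                        n_positions = series@nPositions,
                        clock_res_h = series@clockRes),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeEventSeries
#' @export
readEventSeries <- function(path) {
  df <- utils::read.csv(path)
  meta <- yaml::yaml.load_file(paste0(path, ".yaml"))
  new("EventSeries",
      events = data.frame(position = df$position_id, t = df$t_h,
                          x = df$x_um, y = df$y_um),
      window = meta$window_h, nPositions = meta$n_positions,
      clockRes = meta$clock_res_h)
}
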