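#' @include model.R
NULL

# site coordinates (µm): x along columns, y along rows, 0-based pixel centres
.siteCoords <- function(dims, dx) {
  list(x = matrix(rep((seq_len(dims[2]) - 1) * dx, each = dims[1]),
                  nrow = dims[1]),
       y = matrix(rep((seq_len(dims[1]) - 1) * dx, times = dims[2]),
                  nrow = dims[1]))
}

#' Initialize a spatial ROS field at the lower steady state
#'
#' Every lattice site is set to the lower stable steady state of the ROS
#' balance at the given erastin concentration (cells are allowed to
#' equilibrate before any wave is initiated). The lattice spacing is
#' `cellDiameter + intercellularDistance` (one site per cell).
#'
#' @param erastin erastin concentration (µM); must admit a low steady state,
#'   i.e. lie below the upper fold of the bistable window.
#' @param params a [RosModelParams-class].
#' @param shape integer length-2, grid dimensions `c(rows, cols)`; a 1D chain
#'   is `c(1, N)` (or `c(N, 1)`).
#' @return A [RosField-class] with all sites alive and at the lower steady
#'   state.
#' @examples
#' f <- initField(1, rosModelParams(), c(1, 50))
#' unique(as.vector(rosValues(f)))
#' @export
initField <- function(erastin, params, shape) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  shape <- as.integer(shape)
  ss <- findSteadyStates(erastin, params)
  st <- ss@ros[ss@stability == "stable"]
  if (length(ss@ros) == 1 && ss@ros[1] > params@ec50PositiveFb * 0.5)
    stop("no low steady state at erastin = ", erastin,
         " µM (monostable high); cannot initialize a resting field")
  lower <- min(st)
  uss <- if (length(ss@ros) == 3) ss@ros[2] else NA_real_
  upper <- if (length(ss@ros) == 3) ss@ros[3] else NA_real_
  dx <- params@cellDiameter + params@intercellularDistance
  m <- matrix(lower, shape[1], shape[2])
  new("RosField", ros = m,
      alive = matrix(TRUE, shape[1], shape[2]),
      tAbove = matrix(0, shape[1], shape[2]),
      time = 0, dx = dx, erastin = erastin,
      lowerSS = lower, uss = uss, upperSS = upper,
      deathThreshold = if (is.na(upper)) NA_real_ else 0.9 * upper)
}

# normalize a photoinduction region spec to a logical matrix
.regionMask <- function(field, region) {
  d <- dim(field@ros)
  if (is.logical(region) && is.matrix(region)) {
    if (!identical(dim(region), d)) stop("region mask dimensions mismatch")
    region
  } else if (is.numeric(region)) {
    m <- matrix(FALSE, d[1], d[2])
    m[as.integer(region)] <- TRUE
    m
  } else stop("region must be a logical mask or a vector of site indices")
}

#' Apply photoinduction to a region of the field
#'
#' Raises ROS in the given region, emulating localized blue-light
#' irradiation. The default level, `"above-USS"`, sets the region to 1.05
#' times the unstable steady state, just past the activation threshold.
#'
#' @param field a [RosField-class].
#' @param region logical mask with the field's dimensions, or a vector of
#'   (linear) site indices; must be nonempty.
#' @param level numeric ROS level (µM), or `"above-USS"`.
#' @return The modified [RosField-class].
#' @export
applyPhotoinduction <- function(field, region, level = "above-USS") {
  stopifnot(is(field, "RosField"))
  mask <- .regionMask(field, region)
  if (!any(mask)) stop("photoinduction region is empty")
  if (identical(level, "above-USS")) {
    if (is.na(field@uss))
      stop("'above-USS' requested but no USS exists at erastin = ",
           field@erastin, " µM (monostable regime)")
    level <- 1.05 * field@uss
  }
  stopifnot(is.numeric(level), level >= 0)
  field@ros[mask] <- level
  field
}

# 5-point Laplacian with no-flux (Neumann) boundaries, times 1/dx^2
.laplacian <- function(m, dx) {
  nr <- nrow(m); nc <- ncol(m)
  up    <- m[c(1L, seq_len(nr - 1L)), , drop = FALSE]
  down  <- m[c(seq_len(nr)[-1L], nr), , drop = FALSE]
  left  <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc)[-1L], nc), drop = FALSE]
  (up + down + left + right - 4 * m) / dx^2
}

#' Maximum stable time step of the explicit scheme
#'
#' The diffusion stability bound of the explicit Euler update:
#' `dx^2/(2D)` for a 1D chain, `dx^2/(4D)` for a 2D sheet.
#'
#' @param field a [RosField-class].
#' @param params a [RosModelParams-class].
#' @return Bound in min.
#' @export
stableTimeStep <- function(field, params) {
  d <- dim(field@ros)
  denom <- if (min(d) == 1L) 2 else 4
  field@dx^2 / (denom * params@D)
}

#' Advance the field by one explicit Euler step
#'
#' One update of the reaction-diffusion equation: 5-point Laplacian diffusion
#' with no-flux boundaries plus the reaction rate at each site. Sites at or
#' above the death threshold (90% of the upper steady state of the
#' condition) accumulate exposure time; after 30 min of accumulated exposure
#' a site dies. Dead sites stop producing ROS (positive feedback,
#' GSH removal and basal synthesis are switched off) but keep first-order
#' degradation and diffusive exchange.
#'
#' @param field a [RosField-class].
#' @param dt time step (min); must satisfy [stableTimeStep()].
#' @param params a [RosModelParams-class].
#' @param reactionOn set `FALSE` for a diffusion-only update (useful for
#'   conservation checks).
#' @param deathTime accumulated minutes above threshold that kill a site.
#' @return The advanced [RosField-class].
#' @export
stepField <- function(field, dt, params, reactionOn = TRUE, deathTime = 30) {
  stopifnot(is(field, "RosField"), dt > 0)
  bound <- stableTimeStep(field, params)
  if (dt > bound * (1 + 1e-12))
    stop(sprintf("dt = %g min violates the diffusion stability bound dx^2/(%dD) = %g min",
                 dt, if (min(dim(field@ros)) == 1L) 2L else 4L, bound))
  ros <- field@ros
  lap <- params@D * .laplacian(ros, field@dx)
  if (reactionOn) {
    rate <- reactionRate(ros, field@erastin, params)
    dead <- !field@alive
    if (any(dead))  # production off, degradation and diffusion remain
      rate[dead] <- -params@kDeg * ros[dead]
  } else {
    rate <- 0
  }
  newRos <- pmax(ros + dt * (lap + rate), 0)
  if (reactionOn && !is.na(field@deathThreshold)) {
    above <- field@alive & (newRos >= field@deathThreshold)
    field@tAbove[above] <- field@tAbove[above] + dt
    field@alive[field@tAbove >= deathTime] <- FALSE
  }
  field@ros <- newRos
  field@time <- field@time + dt
  field
}

# distance of every site from a point (µm)
.distFrom <- function(field, centre) {
  co <- .siteCoords(dim(field@ros), field@dx)
  sqrt((co$x - centre[1])^2 + (co$y - centre[2])^2)
}

# front position: farthest crossing site from the centroid (1D), or the 95th
# percentile of crossing-site distances (2D) to resist stragglers
.frontPosition <- function(crossed, dist) {
  if (!any(crossed)) return(NA_real_)
  d <- dist[crossed]
  if (min(dim(crossed)) == 1L) max(d) else unname(stats::quantile(d, 0.95))
}

#' Run a trigger-wave simulation
#'
#' Initializes the field at the lower steady state ([initField()]), applies
#' photoinduction ([applyPhotoinduction()]), and integrates the
#' reaction-diffusion equation with explicit Euler steps of
#' `dtFactor * stableTimeStep()`. The ROS front is the farthest site from
#' the photoinduction centroid whose ROS is at or above the front threshold
#' (the USS when one exists); the death front is defined the same way on
#' dead sites.
#'
#' Recording stops early when the front comes within two lattice sites of
#' the domain boundary, so measured trajectories are free of boundary
#' effects.
#'
#' @param erastin erastin concentration (µM).
#' @param params a [RosModelParams-class].
#' @param shape grid dimensions `c(rows, cols)`.
#' @param photoRegion region passed to [applyPhotoinduction()].
#' @param tEnd simulated time (min).
#' @param photoLevel ROS level of the photoinduced region (µM) or
#'   `"above-USS"`.
#' @param dtFactor fraction of the stability bound used as time step.
#' @param snapshotEvery interval between stored snapshots (min), or `NA`
#'   for none.
#' @param recordEvery interval between trajectory records (min).
#' @param frontThreshold ROS level defining the front (µM); defaults to the
#'   USS, or to half the photoinduction level in the monostable regime.
#' @return A [WaveSimResult-class].
#' @examples
#' \donttest{
#' p <- rosModelParams()
#' sim <- runSimulation(5, p, c(1, 120), photoRegion = 1:5, tEnd = 300)
#' measureSimSpeed(sim)
#' }
#' @export
runSimulation <- function(erastin, params, shape, photoRegion, tEnd,
                          photoLevel = "above-USS", dtFactor = 0.8,
                          snapshotEvery = NA, recordEvery = 5,
                          frontThreshold = NULL) {
  field <- initField(erastin, params, shape)
  field <- applyPhotoinduction(field, photoRegion, photoLevel)
  mask <- .regionMask(field, photoRegion)
  co <- .siteCoords(dim(field@ros), field@dx)
  centre <- c(mean(co$x[mask]), mean(co$y[mask]))
  dist <- .distFrom(field, centre)
  photoRadius <- max(dist[mask])
  if (is.null(frontThreshold)) {
    frontThreshold <- if (!is.na(field@uss)) field@uss else {
      lv <- if (identical(photoLevel, "above-USS"))
        stop("monostable regime: give a numeric photoLevel") else photoLevel
      lv / 2
    }
  }
  dt <- dtFactor * stableTimeStep(field, params)
  nSteps <- ceiling(tEnd / dt)
  maxDist <- max(dist)
  edge <- maxDist - 2 * field@dx

  ts <- fr <- dfr <- numeric(0)
  snaps <- list()
  nextRecord <- 0
  nextSnap <- if (is.na(snapshotEvery)) Inf else 0
  record <- function(field) {
    ts <<- c(ts, field@time)
    fr <<- c(fr, .frontPosition(field@ros >= frontThreshold, dist))
    dfr <<- c(dfr, .frontPosition(!field@alive, dist))
  }
  for (i in seq_len(nSteps)) {
    if (field@time >= nextRecord - 1e-9) {
      record(field)
      nextRecord <- nextRecord + recordEvery
      lastFront <- fr[length(fr)]
      if (!is.na(lastFront) && lastFront >= edge) break
    }
    if (field@time >= nextSnap - 1e-9) {
      snaps[[length(snaps) + 1]] <- field
      nextSnap <- nextSnap + snapshotEvery
    }
    field <- stepField(field, dt, params)
  }
  record(field)
  keep <- !duplicated(ts)
  ts <- ts[keep]; fr <- fr[keep]; dfr <- dfr[keep]
  new("WaveSimResult",
      snapshots = snaps,
      frontTrajectory = data.frame(t = ts, front = fr),
      deathTrajectory = data.frame(t = ts, front = dfr),
      photoCentroid = centre, photoRadius = photoRadius,
      frontThreshold = frontThreshold)
}

#' Measure the asymptotic wave speed of a simulation
#'
#' Least-squares slope of the front trajectory over the last `fitWindow`
#' fraction of the recorded time span (discarding the initial transient).
#' A `"no-wave"` result is returned when the front never left the
#' photoinduced region.
#'
#' @param result a [WaveSimResult-class].
#' @param fitWindow fraction (0, 1] of the trajectory, counted from the end,
#'   used for the fit.
#' @param which `"ros"` or `"death"` front.
#' @return A [SpeedEstimate-class].
#' @export
measureSimSpeed <- function(result, fitWindow = 2 / 3, which = c("ros", "death")) {
  which <- match.arg(which)
  tr <- if (which == "ros") result@frontTrajectory else result@deathTrajectory
  tr <- tr[!is.na(tr$front), ]
  noWave <- new("SpeedEstimate", speed = NA_real_, stderr = NA_real_,
                r2 = NA_real_, fitPoints = data.frame(t = numeric(0),
                                                      y = numeric(0)),
                status = "no-wave")
  if (!nrow(tr) || max(tr$front) <= result@photoRadius + 1e-9) return(noWave)
  t0 <- max(tr$t) - fitWindow * (max(tr$t) - min(tr$t))
  fit <- tr[tr$t >= t0, ]
  if (nrow(fit) < 10 || length(unique(fit$front)) < 2) return(noWave)
  m <- stats::lm(front ~ t, data = fit)
  s <- suppressWarnings(summary(m))  # a noiseless trajectory fits exactly
  new("SpeedEstimate", speed = unname(stats::coef(m)[2]),
      stderr = s$coefficients[2, 2], r2 = s$r.squared,
      fitPoints = data.frame(t = fit$t, y = fit$front), status = "ok")
}

#' Convert simulation snapshots into an image stack
#'
#' Packs the stored ROS snapshots of a simulation into an
#' [ImageStack-class] (one lattice site per pixel, pixel size equal to the
#' lattice spacing), so the image-analysis pipeline (kymographs, outlines,
#' speed estimation) can be applied to simulated waves.
#'
#' @param result a [WaveSimResult-class] run with a finite `snapshotEvery`.
#' @return An [ImageStack-class] with channel `"ros"`.
#' @export
simToImageStack <- function(result) {
  sn <- result@snapshots
  if (length(sn) < 2) stop("need at least two snapshots")
  d <- dim(sn[[1]]@ros)
  fr <- array(0, c(d[1], d[2], length(sn)))
  for (k in seq_along(sn)) fr[, , k] <- sn[[k]]@ros
  dtS <- sn[[2]]@time - sn[[1]]@time
  new("ImageStack", frames = fr, pixelSize = sn[[1]]@dx,
      frameInterval = dtS, channel = "ros")
}

#' Wavefront width and amplitude from simulation snapshots
#'
#' For each pair of consecutive stored snapshots, the width is the distance
#' between the two front positions (consecutive front outlines) and the
#' amplitude is the maximal ROS among the sites lying between them.
#'
#' @param result a [WaveSimResult-class] run with a finite `snapshotEvery`.
#' @return data.frame with columns `t0`, `t1`, `width` (µm), `amplitude`
#'   (µM), one row per snapshot pair with a defined front; plus a `mean`
#'   attribute with the late-half means.
#' @export
measureFrontWidthAmplitude <- function(result) {
  sn <- result@snapshots
  if (length(sn) < 2)
    stop("need at least two snapshots; rerun with snapshotEvery set")
  thr <- result@frontThreshold
  out <- NULL
  for (i in seq_len(length(sn) - 1)) {
    f0 <- sn[[i]]; f1 <- sn[[i + 1]]
    dist <- .distFrom(f0, result@photoCentroid)
    r0 <- .frontPosition(f0@ros >= thr, dist)
    r1 <- .frontPosition(f1@ros >= thr, dist)
    if (is.na(r0) || is.na(r1) || r1 <= r0) next
    between <- dist > r0 & dist <= r1
    if (!any(between)) next
    out <- rbind(out, data.frame(t0 = f0@time, t1 = f1@time,
                                 width = r1 - r0,
                                 amplitude = max(f1@ros[between])))
  }
  if (is.null(out))
    return(structure(data.frame(t0 = numeric(0), t1 = numeric(0),
                                width = numeric(0), amplitude = numeric(0)),
                     mean = c(width = NA_real_, amplitude = NA_real_)))
  late <- out[out$t0 >= stats::median(out$t0), , drop = FALSE]
  structure(out, mean = c(width = mean(late$width),
                          amplitude = mean(late$amplitude)))
}
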