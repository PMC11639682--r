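#' @include AllClasses.R
NULL

#' Accessors for ferrowave classes
#'
#' Small accessor generics for the package's S4 containers. Slot access via
#' `@` is discouraged outside the package.
#'
#' @param object an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rosValues", function(object) standardGeneric("rosValues"))

#' @rdname accessors
#' @export
setGeneric("aliveMask", function(object) standardGeneric("aliveMask"))

#' @rdname accessors
#' @export
setGeneric("simTime", function(object) standardGeneric("simTime"))

#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(object) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("kymoMatrix", function(object) standardGeneric("kymoMatrix"))

#' @rdname accessors
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))

#' @rdname accessors
#' @export
setGeneric("waveSpeed", function(object) standardGeneric("waveSpeed"))

#' @rdname accessors
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

setMethod("rosValues", "RosField", function(object) object@ros)
setMethod("rosValues", "SteadyStateSet", function(object) object@ros)
setMethod("aliveMask", "RosField", function(object) object@alive)
setMethod("simTime", "RosField", function(object) object@time)
setMethod("gridSpacing", "RosField", function(object) object@dx)
setMethod("frames", "ImageStack", function(object) object@frames)
setMethod("pixelSize", "ImageStack", function(object) object@pixelSize)
setMethod("frameInterval", "ImageStack", function(object) object@frameInterval)
setMethod("channelName", "ImageStack", function(object) object@channel)
setMethod("nFrames", "ImageStack", function(object) dim(object@frames)[3])
setMethod("eventTable", "EventSeries", function(object) object@events)
setMethod("kymoMatrix", "Kymograph", function(object) object@matrix)
setMethod("angles", "DeathVectorField", function(object) object@angle)
setMethod("waveSpeed", "SpeedEstimate", function(object) object@speed)
setMethod("fitParams", "DoseResponseFit", function(object) object@params)

setMethod("show", "RosModelParams", function(object) {
  cat("RosModelParams (µM, µm, min)\n")
  cat(sprintf("  D = %g µm²/min, dx = %g µm (cell %g + gap %g)\n",
              object@D, object@cellDiameter + object@intercellularDistance,
              object@cellDiameter, object@intercellularDistance))
  cat(sprintf("  positive fb: k = %g, EC50 = %g, n = %g\n",
              object@kPositiveFb, object@ec50PositiveFb, object@nPositiveFb))
  cat(sprintf("  GSH removal: k = %g, cGSH = %g, EC50[erastin] = %g, EC50 = %g, n = %g\n",
              object@kDNegativeFb, object@cGSH, object@ec50Erastin,
              object@ec50DNegativeFb, object@nDNegativeFb))
  cat(sprintf("  k[deg] = %g /min, k[synth] = %g µM/min\n",
              object@kDeg, object@kSynth))
})

setMethod("show", "SteadyStateSet", function(object) {
  cat(sprintf("SteadyStateSet at erastin = %g µM: %d state(s)\n",
              object@erastin, length(object@ros)))
  for (i in seq_along(object@ros))
    cat(sprintf("  ROS = %.6g µM (%s)\n", object@ros[i], object@stability[i]))
})

setMethod("show", "RosField", function(object) {
  d <- dim(object@ros)
  cat(sprintf("RosField %d x %d sites, dx = %g µm, t = %g min\n",
              d[1], d[2], object@dx, object@time))
  cat(sprintf("  erastin = %g µM; ROS in [%.4g, %.4g] µM; %d dead site(s)\n",
              object@erastin, min(object@ros), max(object@ros),
              sum(!object@alive)))
})

setMethod("show", "WaveSimResult", function(object) {
  cat(sprintf("WaveSimResult: %d snapshot(s), %d trajectory point(s)\n",
              length(object@snapshots), nrow(object@frontTrajectory)))
  if (nrow(object@frontTrajectory))
    cat(sprintf("  ROS front %g -> %g µm over t = %g..%g min\n",
                object@frontTrajectory$front[1],
                utils::tail(object@frontTrajectory$front, 1),
                object@frontTrajectory$t[1],
                utils::tail(object@frontTrajectory$t, 1)))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ImageStack '%s': %d x %d px, %d frame(s), %g µm/px, %g min/frame\n",
              object@channel, d[1], d[2], d[3], object@pixelSize,
              object@frameInterval))
})

setMethod("show", "EventSeries", function(object) {
  cat(sprintf("EventSeries: %d event(s) over %d position(s), window %g h (clock %g h)\n",
              nrow(object@events), object@nPositions, object@window,
              object@clockRes))
})

setMethod("show", "Kymograph", function(object) {
  d <- dim(object@matrix)
  cat(sprintf("Kymograph: %d position(s) x %d frame(s), dy = %g µm, dt = %g min, width %g µm\n",
              d[1], d[2], object@dy, object@dt, object@widthUsed))
})

setMethod("show", "SpeedEstimate", function(object) {
  if (object@status == "no-wave") {
    cat("SpeedEstimate: no wave detected\n")
  } else {
    cat(sprintf("SpeedEstimate: %.4g ± %.2g µm/min (R² = %.4f, %d points)\n",
                object@speed, object@stderr, object@r2,
                nrow(object@fitPoints)))
  }
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("DoseResponseFit '%s' (%s)\n", object@modelName,
              if (object@converged) "converged" else "FAILED"))
  if (length(object@params)) {
    p <- paste(sprintf("%s = %.4g", names(object@params), object@params),
               collapse = ", ")
    cat(" ", p, "\n")
  }
  if (nzchar(object@message)) cat("  ", object@message, "\n")
})

setMethod("show", "LogisticGapFit", function(object) {
  cat(sprintf("LogisticGapFit: beta0 = %.4g, beta1 = %.4g, x50 = %.4g µm%s\n",
              object@beta0, object@beta1, object@x50,
              if (object@separated) " [separated; penalized fit]" else ""))
})
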