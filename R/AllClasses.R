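#' @import methods
NULL

#' Parameters of the bistable ROS reaction-diffusion model
#'
#' Container for all rate constants, Hill parameters and lattice geometry of
#' the cellular ROS balance used throughout the package. Units are fixed
#' package-wide: concentrations in µM, lengths in µm, times in min.
#'
#' The reaction part of the model balances four processes:
#' \itemize{
#'   \item a lumped ROS positive feedback (Fenton chemistry and NADPH-oxidase
#'     signalling as one Hill term): \eqn{k_{pos} \, ROS^{n}/(EC50_{pos}^{n} + ROS^{n})};
#'   \item GSH-mediated ROS removal, a double-negative feedback that erastin
#'     weakens by blocking cystine import. Its strength is
#'     \eqn{k_{d} \, (c_{GSH} + EC50_{era}/(EC50_{era}+E)) / (1 + c_{GSH})},
#'     normalized so that \eqn{k_{d}} is the removal rate at zero erastin, and
#'     it saturates in ROS through \eqn{EC50_{d}^{n}/(EC50_{d}^{n} + ROS^{n})};
#'   \item first-order degradation \eqn{k_{deg} \, ROS};
#'   \item constant basal synthesis \eqn{k_{synth}}.
#' }
#'
#' @slot D diffusion coefficient of the propagating ROS species (µm²/min).
#' @slot kPositiveFb maximal rate of the lumped ROS positive feedback (µM/min).
#' @slot ec50PositiveFb half-activation ROS level of the positive feedback (µM).
#' @slot nPositiveFb Hill coefficient of the positive feedback (>= 1).
#' @slot kDNegativeFb basal GSH-mediated ROS removal rate constant (1/min).
#' @slot cGSH dimensionless basal GSH production independent of cystine import.
#' @slot ec50Erastin erastin concentration half-suppressing cystine import (µM).
#' @slot ec50DNegativeFb ROS level half-saturating the GSH removal arm (µM).
#' @slot nDNegativeFb Hill coefficient of the GSH removal arm (>= 1).
#' @slot kDeg first-order ROS degradation rate (1/min).
#' @slot kSynth basal ROS synthesis rate (µM/min).
#' @slot cellDiameter cell diameter (µm); with \code{intercellularDistance}
#'   this sets the lattice spacing of the spatial simulator.
#' @slot intercellularDistance gap between neighbouring cells (µm).
#' @seealso [rosModelParams()], [reactionRate()], [findSteadyStates()]
#' @export
setClass("RosModelParams",
  representation(
    D = "numeric",
    kPositiveFb = "numeric",
    ec50PositiveFb = "numeric",
    nPositiveFb = "numeric",
    kDNegativeFb = "numeric",
    cGSH = "numeric",
    ec50Erastin = "numeric",
    ec50DNegativeFb = "numeric",
    nDNegativeFb = "numeric",
    kDeg = "numeric",
    kSynth = "numeric",
    cellDiameter = "numeric",
    intercellularDistance = "numeric"
  )
)

setValidity("RosModelParams", function(object) {
  msgs <- character(0)
  pos <- c(
    D = object@D, kPositiveFb = object@kPositiveFb,
    ec50PositiveFb = object@ec50PositiveFb,
    kDNegativeFb = object@kDNegativeFb, cGSH = object@cGSH,
    ec50Erastin = object@ec50Erastin,
    ec50DNegativeFb = object@ec50DNegativeFb,
    kDeg = object@kDeg, kSynth = object@kSynth,
    cellDiameter = object@cellDiameter,
    intercellularDistance = object@intercellularDistance
  )
  if (any(lengths(lapply(slotNames(object), slot, object = object)) != 1L))
    msgs <- c(msgs, "all parameter slots must be length-1 numerics")
  if (any(!is.finite(pos)) || any(pos <= 0))
    msgs <- c(msgs, "all rates, EC50s and lengths must be strictly positive")
  if (object@nPositiveFb < 1 || object@nDNegativeFb < 1)
    msgs <- c(msgs, "Hill coefficients must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Steady states of the ROS balance at one erastin concentration
#'
#' Ordered set of roots of the reaction rate together with their linear
#' stability. In the bistable regime there are three states ordered
#' lower stable < unstable (USS, the activation threshold) < upper stable.
#'
#' @slot erastin erastin concentration (µM).
#' @slot ros steady-state ROS levels (µM), ascending.
#' @slot stability character vector, `"stable"` or `"unstable"`, parallel to
#'   `ros`.
#' @seealso [findSteadyStates()]
#' @export
setClass("SteadyStateSet",
  representation(erastin = "numeric", ros = "numeric", stability = "character")
)

setValidity("SteadyStateSet", function(object) {
  msgs <- character(0)
  if (length(object@ros) != length(object@stability))
    msgs <- c(msgs, "ros and stability must have the same length")
  if (is.unsorted(object@ros, strictly = TRUE))
    msgs <- c(msgs, "ros must be strictly ascending")
  if (!all(object@stability %in% c("stable", "unstable")))
    msgs <- c(msgs, "stability must be 'stable' or 'unstable'")
  if (length(object@ros) == 3 &&
      !identical(object@stability, c("stable", "unstable", "stable")))
    msgs <- c(msgs, "three states must be ordered stable, unstable, stable")
  if (length(msgs)) msgs else TRUE
})

#' Gridded ROS field with per-site viability
#'
#' State of the lattice simulator: ROS concentration, alive/dead flag and the
#' accumulated time each site has spent above the death threshold. One lattice
#' site represents one cell; the spacing is
#' `cellDiameter + intercellularDistance` of the generating
#' [RosModelParams-class].
#'
#' @slot ros matrix of ROS concentrations (µM), sites in rows x columns.
#' @slot alive logical matrix; once a site dies it never reverts.
#' @slot tAbove matrix of accumulated minutes spent at or above the death
#'   threshold.
#' @slot time current simulation time (min).
#' @slot dx lattice spacing (µm).
#' @slot erastin erastin concentration of the condition (µM).
#' @slot lowerSS,uss,upperSS lower stable state, unstable state and upper
#'   stable state of the condition (µM); `uss`/`upperSS` are `NA` in the
#'   monostable regime.
#' @slot deathThreshold ROS level (µM) above which death time accrues
#'   (90% of the upper stable state; `NA` when monostable).
#' @seealso [initField()], [stepField()], [runSimulation()]
#' @export
setClass("RosField",
  representation(
    ros = "matrix", alive = "matrix", tAbove = "matrix",
    time = "numeric", dx = "numeric", erastin = "numeric",
    lowerSS = "numeric", uss = "numeric", upperSS = "numeric",
    deathThreshold = "numeric"
  )
)

setValidity("RosField", function(object) {
  msgs <- character(0)
  d <- dim(object@ros)
  if (!identical(dim(object@alive), d) || !identical(dim(object@tAbove), d))
    msgs <- c(msgs, "ros, alive and tAbove must share dimensions")
  if (any(object@ros < 0))
    msgs <- c(msgs, "ros must be nonnegative everywhere")
  if (!is.logical(object@alive))
    msgs <- c(msgs, "alive must be logical")
  if (object@dx <= 0)
    msgs <- c(msgs, "dx must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Result of a trigger-wave simulation
#'
#' @slot snapshots list of [RosField-class] objects at the requested times.
#' @slot frontTrajectory data.frame with columns `t` (min) and `front` (µm),
#'   the distance of the ROS front from the photoinduction centroid.
#' @slot deathTrajectory same for the death front.
#' @slot photoCentroid numeric length-2, centroid of the photoinduced region
#'   (µm, x then y).
#' @slot photoRadius largest distance from the centroid to a photoinduced
#'   site (µm).
#' @slot frontThreshold ROS level used to define the front (µM).
#' @seealso [runSimulation()], [measureSimSpeed()]
#' @export
setClass("WaveSimResult",
  representation(
    snapshots = "list",
    frontTrajectory = "data.frame",
    deathTrajectory = "data.frame",
    photoCentroid = "numeric",
    photoRadius = "numeric",
    frontThreshold = "numeric"
  )
)

#' Time-lapse intensity stack with physical calibration
#'
#' A T-frame grayscale image stack stored as an H x W x T array, with the
#' physical pixel size and frame interval needed by all quantifications.
#'
#' @slot frames numeric array, dim H x W x T, nonnegative finite intensities.
#' @slot pixelSize pixel edge length (µm).
#' @slot frameInterval time between frames (min).
#' @slot channel one of `"death"`, `"ros"`, `"lipid"`.
#' @seealso [generateWaveStack()], [buildKymograph()], [waveOutline()]
#' @export
setClass("ImageStack",
  representation(
    frames = "array", pixelSize = "numeric",
    frameInterval = "numeric", channel = "character"
  )
)

setValidity("ImageStack", function(object) {
  msgs <- character(0)
  if (length(dim(object@frames)) != 3)
    msgs <- c(msgs, "frames must be an H x W x T array")
  if (any(!is.finite(object@frames)))
    msgs <- c(msgs, "intensities must be finite")
  if (object@pixelSize <= 0 || object@frameInterval <= 0)
    msgs <- c(msgs, "pixelSize and frameInterval must be positive")
  if (!object@channel %in% c("death", "ros", "lipid"))
    msgs <- c(msgs, "channel must be 'death', 'ros' or 'lipid'")
  if (length(msgs)) msgs else TRUE
})

#' Spontaneous initiation events across imaging positions
#'
#' Timestamped spontaneous ferroptosis-initiation events, one record per
#' event, across a set of imaging positions observed for a common window.
#' Event times live on a discrete acquisition clock of resolution `clockRes`.
#'
#' @slot events data.frame with columns `position` (integer id), `t` (h),
#'   `x`, `y` (µm within the position's field).
#' @slot window observation window per position (h).
#' @slot nPositions number of positions (zero-event positions count).
#' @slot clockRes acquisition clock resolution (h).
#' @seealso [generateInitiationSeries()], [initiationStatistics()]
#' @export
setClass("EventSeries",
  representation(
    events = "data.frame", window = "numeric",
    nPositions = "numeric", clockRes = "numeric"
  )
)

setValidity("EventSeries", function(object) {
  msgs <- character(0)
  need <- c("position", "t", "x", "y")
  if (!all(need %in% names(object@events)))
    msgs <- c(msgs, "events needs columns position, t, x, y")
  else if (nrow(object@events) &&
           (any(object@events$t < 0) || any(object@events$t > object@window)))
    msgs <- c(msgs, "event times must lie within [0, window]")
  if (object@window <= 0 || object@nPositions < 1 || object@clockRes <= 0)
    msgs <- c(msgs, "window, nPositions and clockRes must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Space-time kymograph along a propagation axis
#'
#' @slot matrix space x time intensity matrix; rows are positions along the
#'   propagation axis, columns are frames. Each entry is the maximum signal
#'   over the transverse width at that position and frame.
#' @slot dy spatial step along the axis (µm per row).
#' @slot dt time step (min per column).
#' @slot widthUsed transverse width actually aggregated (µm).
#' @seealso [buildKymograph()], [estimateWaveSpeed()]
#' @export
setClass("Kymograph",
  representation(matrix = "matrix", dy = "numeric", dt = "numeric",
                 widthUsed = "numeric")
)

#' Cell-death progression vector field
#'
#' Direction and magnitude of local death progression between two consecutive
#' death outlines. Angles are in radians within (-pi, pi], measured in image
#' coordinates (x along columns, y along rows).
#'
#' @slot angle matrix of angles (radians); `NA` where the magnitude is
#'   negligible.
#' @slot magnitude matrix of gradient magnitudes (arbitrary units).
#' @slot pixelSize pixel edge length (µm).
#' @seealso [deathVectorField()], [vectorEntropy()]
#' @export
setClass("DeathVectorField",
  representation(angle = "matrix", magnitude = "matrix", pixelSize = "numeric")
)

setValidity("DeathVectorField", function(object) {
  a <- object@angle
  if (!identical(dim(a), dim(object@magnitude)))
    return("angle and magnitude must share dimensions")
  if (any(!is.na(a) & (a <= -pi - 1e-9 | a > pi + 1e-9)))
    return("angles must lie in (-pi, pi]")
  TRUE
})

#' Wave-speed estimate from a linear front fit
#'
#' @slot speed estimated speed (µm/min); `NA` when no wave was detected.
#' @slot stderr standard error of the slope (µm/min).
#' @slot r2 R-squared of the linear fit.
#' @slot fitPoints data.frame of the (t, y) points entering the fit
#'   (min, µm).
#' @slot status `"ok"` or `"no-wave"`.
#' @seealso [estimateWaveSpeed()], [measureSimSpeed()]
#' @export
setClass("SpeedEstimate",
  representation(speed = "numeric", stderr = "numeric", r2 = "numeric",
                 fitPoints = "data.frame", status = "character")
)

#' Fitted dose-response model of trigger-wave speed
#'
#' @slot modelName `"michaelian_inh"`, `"michaelian_act"` or `"biphasic"`.
#' @slot params named fitted parameters: `y0`, `yM`, `K` for the Michaelian
#'   forms; `y0`, `yM`, `f1`, `K1`, `K2` (with `K1 < K2`) for the biphasic
#'   form.
#' @slot cov parameter covariance matrix (empty when the fit failed).
#' @slot data data.frame of the fitted (dose, speed) observations.
#' @slot converged logical.
#' @slot message diagnostic message; for failures it reports the initial
#'   guesses used.
#' @seealso [fitMichaelianInhibition()], [predictDose()]
#' @export
setClass("DoseResponseFit",
  representation(modelName = "character", params = "numeric", cov = "matrix",
                 data = "data.frame", converged = "logical",
                 message = "character")
)

#' Fitted logistic model of gap-crossing probability
#'
#' Models the probability that a trigger wave crosses a cell-free gap of
#' width x as p(x) = 1/(1 + exp(-(beta0 + beta1 x))).
#'
#' @slot beta0,beta1 fitted coefficients.
#' @slot cov 2x2 coefficient covariance matrix.
#' @slot x50 gap width at which the crossing probability is 0.5 (µm),
#'   -beta0/beta1.
#' @slot x50se delta-method standard error of `x50`.
#' @slot separated logical; `TRUE` when the data were completely separated
#'   and a ridge-penalized fit was used.
#' @slot data fitted (width, passed) observations.
#' @seealso [fitLogisticGap()]
#' @export
setClass("LogisticGapFit",
  representation(beta0 = "numeric", beta1 = "numeric", cov = "matrix",
                 x50 = "numeric", x50se = "numeric", separated = "logical",
                 data = "data.frame")
)
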