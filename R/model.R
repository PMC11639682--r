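#' @include AllClasses.R AllGenerics.R
NULL

#' Construct model parameters
#'
#' Builds a [RosModelParams-class] object. The defaults are the reference
#' parameter set of the cellular ROS model: `D = 178` µm²/min,
#' `kPositiveFb = 1.2` µM/min, `ec50PositiveFb = 1` µM, `nPositiveFb = 3`,
#' `kDNegativeFb = 1.5` /min, `cGSH = 0.1`, `ec50Erastin = 0.27` µM,
#' `ec50DNegativeFb = 2` µM, `nDNegativeFb = 3`, `kDeg = 0.26` /min,
#' `kSynth = 0.1` µM/min, `cellDiameter = 16` µm,
#' `intercellularDistance = 5` µm. Under these defaults the single-cell ROS
#' balance is monostable (low) below about 0.39 µM erastin, bistable between
#' about 0.39 and 11.7 µM, and monostable (high) above.
#'
#' @param D,kPositiveFb,ec50PositiveFb,nPositiveFb,kDNegativeFb,cGSH
#'   see [RosModelParams-class].
#' @param ec50Erastin,ec50DNegativeFb,nDNegativeFb,kDeg,kSynth see
#'   [RosModelParams-class].
#' @param cellDiameter,intercellularDistance lattice geometry (µm).
#' @return A validated [RosModelParams-class] object.
#' @examples
#' p <- rosModelParams()
#' reactionRate(0, 0, p)  # k_synth alone: 0.1 µM/min
#' @export
rosModelParams <- function(D = 178, kPositiveFb = 1.2, ec50PositiveFb = 1,
                           nPositiveFb = 3, kDNegativeFb = 1.5, cGSH = 0.1,
                           ec50Erastin = 0.27, ec50DNegativeFb = 2,
                           nDNegativeFb = 3, kDeg = 0.26, kSynth = 0.1,
                           cellDiameter = 16, intercellularDistance = 5) {
  new("RosModelParams", D = D, kPositiveFb = kPositiveFb,
      ec50PositiveFb = ec50PositiveFb, nPositiveFb = nPositiveFb,
      kDNegativeFb = kDNegativeFb, cGSH = cGSH, ec50Erastin = ec50Erastin,
      ec50DNegativeFb = ec50DNegativeFb, nDNegativeFb = nDNegativeFb,
      kDeg = kDeg, kSynth = kSynth, cellDiameter = cellDiameter,
      intercellularDistance = intercellularDistance)
}

.paramFields <- c("D", "kPositiveFb", "ec50PositiveFb", "nPositiveFb",
                  "kDNegativeFb", "cGSH", "ec50Erastin", "ec50DNegativeFb",
                  "nDNegativeFb", "kDeg", "kSynth", "cellDiameter",
                  "intercellularDistance")

#' Read / write model parameters as a flat YAML or JSON config
#'
#' The config is a flat mapping with exactly the slot names of
#' [RosModelParams-class]. The format is chosen from the file extension
#' (`.yaml`/`.yml` or `.json`).
#'
#' @param params a [RosModelParams-class] object.
#' @param path file path.
#' @return `readModelParams` returns a [RosModelParams-class];
#'   `writeModelParams` returns `path` invisibly.
#' @export
writeModelParams <- function(params, path) {
  stopifnot(is(params, "RosModelParams"))
  vals <- lapply(.paramFields, function(f) slot(params, f))
  names(vals) <- .paramFields
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste0("{\n", paste(sprintf('  "%s": %.17g', names(vals),
                                       unlist(vals)), collapse = ",\n"),
                  "\n}\n")
    writeLines(txt, path)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @rdname writeModelParams
#' @export
readModelParams <- function(path) {
  vals <- yaml::yaml.load_file(path)  # YAML is a superset of JSON
  missing <- setdiff(.paramFields, names(vals))
  if (length(missing))
    stop("config is missing fields: ", paste(missing, collapse = ", "))
  do.call(rosModelParams, vals[.paramFields])
}

# erastin modulation of the GSH removal arm, normalized to 1 at E = 0 so that
# kDNegativeFb is the basal removal rate
.erastinFactor <- function(erastin, params) {
  (params@cGSH + params@ec50Erastin / (params@ec50Erastin + erastin)) /
    (1 + params@cGSH)
}

#' Reaction rate of the well-mixed ROS balance
#'
#' Net ROS production rate (µM/min) of a single well-mixed cell, i.e. the
#' reaction part of the spatial model with diffusion excluded:
#' positive feedback - GSH-mediated removal - degradation + basal synthesis.
#' See [RosModelParams-class] for the functional form of each term.
#'
#' @param ros ROS concentration(s), µM; vectorized.
#' @param erastin erastin concentration, µM (scalar).
#' @param params a [RosModelParams-class].
#' @return Net rate(s), µM/min.
#' @examples
#' p <- rosModelParams()
#' reactionRate(1, 1, p)
#' @export
reactionRate <- function(ros, erastin, params) {
  stopifnot(is(params, "RosModelParams"))
  if (any(ros < 0) || any(erastin < 0))
    stop("ros and erastin must be nonnegative")
  np <- params@nPositiveFb
  nd <- params@nDNegativeFb
  rp <- ros^np
  rd <- ros^nd
  pos <- params@kPositiveFb * rp / (params@ec50PositiveFb^np + rp)
  kdn <- params@ec50DNegativeFb^nd
  neg <- params@kDNegativeFb * .erastinFactor(erastin, params) *
    kdn / (kdn + rd) * ros
  pos - neg - params@kDeg * ros + params@kSynth
}

#' Derivative of the reaction rate with respect to ROS
#'
#' Analytic d(rate)/d(ROS) used for linear stability classification
#' (negative at a root means the steady state is stable).
#'
#' @inheritParams reactionRate
#' @return Derivative value(s), 1/min.
#' @export
reactionRateDeriv <- function(ros, erastin, params) {
  stopifnot(is(params, "RosModelParams"))
  if (any(ros < 0) || any(erastin < 0))
    stop("ros and erastin must be nonnegative")
  np <- params@nPositiveFb
  nd <- params@nDNegativeFb
  kp <- params@ec50PositiveFb^np
  kd <- params@ec50DNegativeFb^nd
  rp <- ros^np
  rd <- ros^nd
  dpos <- params@kPositiveFb * np * kp * ros^(np - 1) / (kp + rp)^2
  dneg <- params@kDNegativeFb * .erastinFactor(erastin, params) *
    kd * ((kd + rd) - nd * rd) / (kd + rd)^2
  dpos - dneg - params@kDeg
}

# Evaluation grid for root bracketing: hybrid log + linear covering [0, rosMax].
.rosGrid <- function(rosMax, n = 512) {
  nl <- n %/% 2
  sort(unique(c(0, 10^seq(-4, log10(rosMax), length.out = nl),
                seq(0, rosMax, length.out = n - nl))))
}

# Bisection to |rate| < tol (falling back on bracket collapse).
.bisectRoot <- function(lo, hi, erastin, params, tol) {
  flo <- reactionRate(lo, erastin, params)
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- reactionRate(mid, erastin, params)
    if (abs(fm) < tol || (hi - lo) < 1e-14) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else hi <- mid
  }
  (lo + hi) / 2
}

# Root set of the reaction rate on [0, rosMax]; catches near-tangent root
# pairs (close to a fold) by refining local extrema of the rate.
.reactionRoots <- function(erastin, params, rosMax, tol) {
  grid <- .rosGrid(rosMax)
  v <- reactionRate(grid, erastin, params)
  roots <- numeric(0)
  sc <- which(diff(sign(v)) != 0 & v[-length(v)] != 0)
  for (j in sc)
    roots <- c(roots, .bisectRoot(grid[j], grid[j + 1], erastin, params, tol))
  roots <- c(roots, grid[v == 0])
  # near-fold pairs: a local extremum that pokes through zero between grid
  # points can hide two sign changes
  ds <- diff(sign(diff(v)))
  ext <- which(ds != 0) + 1L
  for (j in ext) {
    lo <- grid[max(1L, j - 1L)]; hi <- grid[min(length(grid), j + 1L)]
    maximum <- ds[j - 1L] < 0
    o <- stats::optimize(function(r) reactionRate(r, erastin, params),
                         c(lo, hi), maximum = maximum, tol = 1e-12)
    xe <- if (maximum) o$maximum else o$minimum
    fe <- o$objective
    flo <- reactionRate(lo, erastin, params)
    fhi <- reactionRate(hi, erastin, params)
    if (is.finite(fe) && fe != 0 && sign(flo) == sign(fhi) &&
        sign(fe) != sign(flo)) {
      roots <- c(roots, .bisectRoot(lo, xe, erastin, params, tol),
                 .bisectRoot(xe, hi, erastin, params, tol))
    }
  }
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-8)]
  roots
}

#' Steady states of the ROS balance at one erastin concentration
#'
#' Finds all roots of [reactionRate()] in `[0, rosMax]` by a sign-change scan
#' on a hybrid log/linear grid followed by bisection, and classifies each
#' root's stability from the analytic derivative (with a finite-difference
#' fallback, step 1e-6 µM, should the analytic derivative be non-finite).
#'
#' @param erastin erastin concentration (µM).
#' @param params a [RosModelParams-class].
#' @param rosMax upper end of the search bracket (µM); must exceed the upper
#'   steady state (default 10 is ample for the reference parameters).
#' @param tol bisection stops when `|reactionRate| < tol` (µM/min).
#' @return A [SteadyStateSet-class].
#' @examples
#' findSteadyStates(1, rosModelParams())  # 3 states: low, USS, high
#' @export
findSteadyStates <- function(erastin, params, rosMax = 10, tol = 1e-10) {
  stopifnot(rosMax > 0, tol > 0)
  if (reactionRate(rosMax, erastin, params) >= 0)
    stop("rosMax = ", rosMax, " does not bracket the upper steady state; ",
         "the reaction rate is still nonnegative there")
  roots <- .reactionRoots(erastin, params, rosMax, tol)
  if (!length(roots)) {
    grid <- .rosGrid(rosMax)
    v <- reactionRate(grid, erastin, params)
    stop("failed to bracket any root on [0, ", rosMax, "]; rate range [",
         min(v), ", ", max(v), "] over ", length(grid), " grid points")
  }
  dv <- reactionRateDeriv(roots, erastin, params)
  bad <- !is.finite(dv)
  if (any(bad)) {
    h <- 1e-6
    dv[bad] <- (reactionRate(roots[bad] + h, erastin, params) -
                  reactionRate(pmax(roots[bad] - h, 0), erastin, params)) /
      (h + pmin(roots[bad], h))
  }
  new("SteadyStateSet", erastin = erastin, ros = roots,
      stability = ifelse(dv < 0, "stable", "unstable"))
}

# root count only (no refinement); used by the bifurcation scan
.countRoots <- function(erastin, params, rosMax) {
  length(.reactionRoots(erastin, params, rosMax, tol = 1e-9))
}

#' Saddle-node bifurcation scan over erastin
#'
#' Scans erastin over `[0, eMax]`, counting ROS steady states at each value,
#' and refines by bisection the two fold points where the count changes
#' 1 -> 3 (lower boundary of the bistable window) and 3 -> 1 (upper
#' boundary). Boundaries are reported at the midpoint of the final bisection
#' bracket, refined to within `±boundaryTol`.
#'
#' With the default parameters the window is approximately 0.39–11.7 µM
#' erastin.
#'
#' @param params a [RosModelParams-class].
#' @param eMax upper end of the scanned erastin range (µM).
#' @param resolution scan step (µM).
#' @param boundaryTol half-width of the final bisection bracket (µM).
#' @param rosMax ROS search bracket passed to the root counter (µM).
#' @param curveBy erastin step of the returned steady-state curve (µM);
#'   `NA` suppresses the curve.
#' @return A list with elements
#'   \item{bistable}{logical; `FALSE` when no bistable window was found, in
#'     which case `eLower`/`eUpper` are `NA` (a structured result, not an
#'     error).}
#'   \item{eLower, eUpper}{fold-point erastin concentrations (µM).}
#'   \item{curve}{data.frame with columns `erastin`, `rosLow`, `rosUss`,
#'     `rosHigh` (`NA` where monostable; the single state is reported in
#'     `rosLow` below the window and in `rosHigh` above it).}
#' @examples
#' \donttest{
#' scan <- bifurcationScan(rosModelParams())
#' c(scan$eLower, scan$eUpper)
#' }
#' @export
bifurcationScan <- function(params, eMax = 20, resolution = 0.01,
                            boundaryTol = 0.005, rosMax = 10, curveBy = 0.1) {
  stopifnot(eMax > 0, resolution > 0, boundaryTol > 0)
  es <- seq(0, eMax, by = resolution)
  counts <- vapply(es, .countRoots, integer(1), params = params,
                   rosMax = rosMax)
  change <- which(diff(counts) != 0)
  refine <- function(lo, hi) {
    clo <- .countRoots(lo, params, rosMax)
    while ((hi - lo) / 2 > boundaryTol) {
      mid <- (lo + hi) / 2
      if (.countRoots(mid, params, rosMax) == clo) lo <- mid else hi <- mid
    }
    # one extra halving so the midpoint is within boundaryTol of the fold
    mid <- (lo + hi) / 2
    if (.countRoots(mid, params, rosMax) == clo) lo <- mid else hi <- mid
    (lo + hi) / 2
  }
  eLower <- NA_real_
  eUpper <- NA_real_
  for (j in change) {
    b <- refine(es[j], es[j + 1])
    if (counts[j] == 1 && counts[j + 1] == 3) eLower <- b
    if (counts[j] == 3 && counts[j + 1] == 1) eUpper <- b
  }
  curve <- NULL
  if (!is.na(curveBy)) {
    ec <- sort(unique(c(seq(0, eMax, by = curveBy),
                        eLower, eUpper)))
    ec <- ec[!is.na(ec)]
    curve <- do.call(rbind, lapply(ec, function(e) {
      ss <- findSteadyStates(e, params, rosMax = rosMax)
      r <- ss@ros
      if (length(r) == 3) {
        data.frame(erastin = e, rosLow = r[1], rosUss = r[2], rosHigh = r[3])
      } else if (!is.na(eLower) && e < eLower) {
        data.frame(erastin = e, rosLow = r[1], rosUss = NA_real_,
                   rosHigh = NA_real_)
      } else if (!is.na(eUpper) && e > eUpper) {
        data.frame(erastin = e, rosLow = NA_real_, rosUss = NA_real_,
                   rosHigh = r[1])
      } else {
        data.frame(erastin = e, rosLow = r[1], rosUss = NA_real_,
                   rosHigh = NA_real_)
      }
    }))
  }
  list(bistable = !is.na(eLower) || !is.na(eUpper),
       eLower = eLower, eUpper = eUpper, curve = curve)
}
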