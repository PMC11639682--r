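#' @include AllClasses.R AllGenerics.R synthetic.R
NULL

.failedFit <- function(modelName, data, start, err) {
  new("DoseResponseFit", modelName = modelName, params = numeric(0),
      cov = matrix(numeric(0), 0, 0), data = data, converged = FALSE,
      message = paste0("fit failed (", conditionMessage(err),
                       "); initial guesses: ",
                       paste(sprintf("%s = %.4g", names(start),
                                     unlist(start)), collapse = ", ")))
}

.nlsFit <- function(modelName, formula, data, start, lower, upper) {
  res <- tryCatch({
    fit <- minpack.lm::nlsLM(formula, data = data, start = start,
                             lower = lower, upper = upper,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 500))
    cv <- tryCatch(stats::vcov(fit), error = function(e) {
      k <- length(stats::coef(fit))
      matrix(NA_real_, k, k,
             dimnames = list(names(stats::coef(fit)),
                             names(stats::coef(fit))))
    })
    list(coef = stats::coef(fit), cov = cv)
  }, error = function(e) e)
  if (inherits(res, "error")) return(.failedFit(modelName, data, start, res))
  new("DoseResponseFit", modelName = modelName,
      params = res$coef, cov = res$cov, data = data,
      converged = TRUE, message = "")
}

#' Fit Michaelian inhibition dose-response
#'
#' Nonlinear least-squares fit of `speed = y0 + (yM - y0) K/(K + dose)`
#' (speed falls from `yM` at zero dose towards `y0`, half-way at
#' `dose = K`). Initial guesses are deterministic and data-driven:
#' `y0 = min(speed)`, `yM = max(speed)`, `K = median(dose)`.
#'
#' @param doses nonnegative dose vector; at least 4 distinct levels
#'   including 0.
#' @param speeds observed wave speeds (µm/min).
#' @return A [DoseResponseFit-class]; non-convergence yields a structured
#'   failure carrying the initial guesses, not an error.
#' @export
fitMichaelianInhibition <- function(doses, speeds) {
  .checkDose(doses, speeds, 4)
  d <- data.frame(dose = doses, speed = speeds)
  start <- list(y0 = min(speeds), yM = max(speeds),
                K = max(stats::median(doses), 1e-6))
  .nlsFit("michaelian_inh", speed ~ y0 + (yM - y0) * K / (K + dose), d,
          start, lower = c(-Inf, -Inf, 1e-9), upper = rep(Inf, 3))
}

#' Fit Michaelian activation dose-response
#'
#' As [fitMichaelianInhibition()] but for
#' `speed = y0 + (yM - y0) dose/(K + dose)` (speed rises from `y0` at zero
#' dose towards the plateau `yM`).
#'
#' @inheritParams fitMichaelianInhibition
#' @return A [DoseResponseFit-class].
#' @export
fitMichaelianActivation <- function(doses, speeds) {
  .checkDose(doses, speeds, 4)
  d <- data.frame(dose = doses, speed = speeds)
  start <- list(y0 = min(speeds), yM = max(speeds),
                K = max(stats::median(doses), 1e-6))
  .nlsFit("michaelian_act", speed ~ y0 + (yM - y0) * dose / (K + dose), d,
          start, lower = c(-Inf, -Inf, 1e-9), upper = rep(Inf, 3))
}

#' Fit biphasic inhibition dose-response
#'
#' Two-site inhibition
#' `speed = y0 + yM (1 - f1 dose/(K1+dose) - (1-f1) dose/(K2+dose))` with
#' `0 <= f1 <= 1`. Identifiability is enforced by ordering `K1 < K2` after
#' the fit (swapping and replacing `f1` by `1 - f1` if needed); a
#' near-degenerate fit with `K1` within 1% of `K2` is flagged in the
#' message. Starts: `y0 = min(speed)`, `yM = range of speed`, `f1 = 0.5`,
#' `K1`/`K2` at the dose quartiles.
#'
#' @inheritParams fitMichaelianInhibition
#' @param doses at least 6 distinct levels including 0.
#' @return A [DoseResponseFit-class].
#' @export
fitBiphasicInhibition <- function(doses, speeds) {
  .checkDose(doses, speeds, 6)
  d <- data.frame(dose = doses, speed = speeds)
  q <- stats::quantile(doses[doses > 0], c(0.25, 0.75), names = FALSE)
  start <- list(y0 = min(speeds), yM = max(speeds) - min(speeds), f1 = 0.5,
                K1 = max(q[1], 1e-6), K2 = max(q[2], 2e-6))
  fit <- .nlsFit("biphasic",
                 speed ~ y0 + yM * (1 - f1 * dose / (K1 + dose) -
                                      (1 - f1) * dose / (K2 + dose)),
                 d, start,
                 lower = c(-Inf, -Inf, 0, 1e-9, 1e-9),
                 upper = c(Inf, Inf, 1, Inf, Inf))
  if (fit@converged) {
    p <- fit@params
    if (p["K1"] > p["K2"]) {
      nm <- c("y0", "yM", "f1", "K1", "K2")
      perm <- c("y0", "yM", "f1", "K2", "K1")
      cv <- fit@cov[perm, perm]
      p <- p[perm]
      names(p) <- nm
      p["f1"] <- 1 - p["f1"]
      # f1 -> 1 - f1 flips the sign of its cross-covariances
      cv[3, -3] <- -cv[3, -3]
      cv[-3, 3] <- -cv[-3, 3]
      dimnames(cv) <- list(nm, nm)
      fit@params <- p
      fit@cov <- cv
    }
    if (abs(fit@params["K1"] - fit@params["K2"]) <
        0.01 * fit@params["K2"])
      fit@message <- "K1 ~ K2: biphasic fit is near-degenerate"
  }
  fit
}

.checkDose <- function(doses, speeds, minLevels) {
  if (length(doses) != length(speeds))
    stop("doses and speeds must have the same length")
  if (any(doses < 0)) stop("doses must be nonnegative")
  if (length(unique(doses)) < minLevels)
    stop("need at least ", minLevels, " distinct dose levels")
  if (!any(doses == 0)) stop("a zero-dose level is required")
  invisible(TRUE)
}

#' Predict from a dose-response fit with 95% confidence band
#'
#' Pointwise 95% confidence band by first-order (delta-method) propagation
#' of the parameter covariance through the model.
#'
#' @param fit a converged [DoseResponseFit-class].
#' @param doses doses at which to predict.
#' @return data.frame with columns `dose`, `fit`, `lower`, `upper`.
#' @export
predictDose <- function(fit, doses) {
  stopifnot(is(fit, "DoseResponseFit"))
  if (!fit@converged) stop("cannot predict from a failed fit")
  p <- fit@params
  f <- switch(fit@modelName,
    michaelian_inh = function(q, x)
      michaelianInhibition(x, q[1], q[2], q[3]),
    michaelian_act = function(q, x)
      michaelianActivation(x, q[1], q[2], q[3]),
    biphasic = function(q, x)
      biphasicInhibition(x, q[1], q[2], q[3], q[4], q[5]))
  yhat <- f(p, doses)
  se <- vapply(doses, function(x) {
    g <- numeric(length(p))
    h <- pmax(abs(p) * 1e-6, 1e-9)
    for (i in seq_along(p)) {
      up <- p; up[i] <- up[i] + h[i]
      dn <- p; dn[i] <- dn[i] - h[i]
      g[i] <- (f(up, x) - f(dn, x)) / (2 * h[i])
    }
    sqrt(max(0, drop(t(g) %*% fit@cov %*% g)))
  }, numeric(1))
  data.frame(dose = doses, fit = yhat,
             lower = yhat - 1.96 * se, upper = yhat + 1.96 * se)
}

#' Fit the logistic gap-crossing model
#'
#' Maximum-likelihood logistic regression of the binary outcome
#' "wave crossed the gap" on gap width:
#' `p(x) = 1/(1 + exp(-(beta0 + beta1 x)))`. Complete separation — the two
#' outcome classes do not overlap along the gap width (or one class is
#' absent), a glm failure, or a diverging coefficient (magnitude above
#' 1e3) — is flagged and a ridge-penalized fit (penalty 1e-4 on the squared
#' coefficients) is used instead. `x50 = -beta0/beta1` is the gap width
#' crossed with probability one half.
#'
#' @param gapWidths gap widths (µm).
#' @param passed 0/1 outcomes; both outcomes should be present.
#' @return A [LogisticGapFit-class].
#' @examples
#' set.seed(1)
#' w <- runif(38, 35, 380)
#' y <- rbinom(38, 1, plogis(8 - 0.05 * w))
#' fitLogisticGap(w, y)
#' @export
fitLogisticGap <- function(gapWidths, passed) {
  stopifnot(length(gapWidths) == length(passed),
            all(passed %in% c(0, 1)))
  if (length(unique(passed)) < 2)
    warning("only one outcome present: data are completely separated")
  d <- data.frame(x = gapWidths, y = passed)
  g <- tryCatch(
    suppressWarnings(stats::glm(y ~ x, family = stats::binomial(), data = d)),
    error = function(e) NULL)
  # in one dimension, complete separation means the outcome classes do not
  # overlap along x (or one class is absent)
  oneClass <- length(unique(passed)) < 2
  noOverlap <- !oneClass &&
    (min(d$x[d$y == 0]) > max(d$x[d$y == 1]) ||
       min(d$x[d$y == 1]) > max(d$x[d$y == 0]))
  separated <- oneClass || noOverlap || is.null(g) || !g$converged ||
    any(abs(stats::coef(g)) > 1e3)
  if (!separated) {
    beta <- stats::coef(g)
    cv <- stats::vcov(g)
  } else {
    # ridge-penalized logistic likelihood keeps the fit finite under
    # complete separation
    nll <- function(b) {
      eta <- b[1] + b[2] * d$x
      -sum(d$y * eta - log1p(exp(eta))) + 1e-4 * sum(b^2) / 2
    }
    o <- stats::optim(c(0, 0), nll, method = "BFGS", hessian = TRUE)
    beta <- o$par
    cv <- tryCatch(solve(o$hessian), error = function(e)
      matrix(NA_real_, 2, 2))
  }
  b0 <- unname(beta[1]); b1 <- unname(beta[2])
  x50 <- if (b1 != 0) -b0 / b1 else NA_real_
  x50se <- if (!is.na(x50) && all(is.finite(cv))) {
    gr <- c(-1 / b1, b0 / b1^2)
    sqrt(max(0, drop(t(gr) %*% cv %*% gr)))
  } else NA_real_
  new("LogisticGapFit", beta0 = b0, beta1 = b1, cov = cv, x50 = x50,
      x50se = x50se, separated = separated,
      data = data.frame(width = gapWidths, passed = passed))
}

#' Diffusion distance
#'
#' Root-mean-square displacement of a diffusing molecule, `d = sqrt(2 D t)`.
#' Unlike a trigger wave's linear advance, diffusive spread is sublinear in
#' time, which is why diffusion alone cannot account for millimetre-scale
#' propagation at constant speed.
#'
#' @param D diffusion coefficient (µm²/s).
#' @param t time (s); vectorized.
#' @return Distance (µm).
#' @examples
#' diffusionDistance(200, 1)  # calcium, 1 s: 20 µm
#' @export
diffusionDistance <- function(D, t) {
  if (any(D < 0) || any(t < 0)) stop("D and t must be nonnegative")
  sqrt(2 * D * t)
}
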