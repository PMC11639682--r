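test_that("noiseless dose-response data are recovered to 4 significant digits", {
  doses <- c(0, 0.5, 1, 2.5, 5, 10, 25, 50, 100, 200)
  inh <- generateDoseResponse("michaelian_inh", list(y0 = 1, yM = 5, K = 10),
                              doses)
  f <- fitMichaelianInhibition(inh$dose, inh$speed)
  expect_true(f@converged)
  expect_equal(unname(fitParams(f)), c(1, 5, 10), tolerance = 1e-4)

  act <- generateDoseResponse("michaelian_act", list(y0 = 1, yM = 9, K = 4),
                              doses)
  fa <- fitMichaelianActivation(act$dose, act$speed)
  expect_equal(unname(fitParams(fa)), c(1, 9, 4), tolerance = 1e-4)

  bip <- generateDoseResponse("biphasic",
                              list(y0 = 1, yM = 4, f1 = 0.6, K1 = 2,
                                   K2 = 50), doses)
  fb <- fitBiphasicInhibition(bip$dose, bip$speed)
  expect_equal(unname(fitParams(fb)), c(1, 4, 0.6, 2, 50), tolerance = 1e-3)
  # mean residual vanishes for noiseless inputs
  pred <- predictDose(fb, doses)
  expect_lt(abs(mean(pred$fit - bip$speed)), 1e-6 * diff(range(bip$speed)))
})

test_that("fitted curves honour the model's landmark values", {
  doses <- c(0, 1, 2, 5, 10, 20, 50)
  inh <- generateDoseResponse("michaelian_inh", list(y0 = 2, yM = 8, K = 5),
                              doses)
  f <- fitMichaelianInhibition(inh$dose, inh$speed)
  p <- fitParams(f)
  expect_equal(predictDose(f, 0)$fit, unname(p["yM"]))         # x = 0 -> yM
  expect_equal(predictDose(f, unname(p["K"]))$fit,
               unname((p["y0"] + p["yM"]) / 2))                # x = K -> midpoint
  act <- generateDoseResponse("michaelian_act", list(y0 = 2, yM = 8, K = 5),
                              doses)
  fa <- fitMichaelianActivation(act$dose, act$speed)
  expect_equal(predictDose(fa, 0)$fit, unname(fitParams(fa)["y0"]))
  bip <- generateDoseResponse("biphasic",
                              list(y0 = 1, yM = 4, f1 = 0.5, K1 = 1,
                                   K2 = 30), c(0, 0.5, 1, 3, 10, 30, 100))
  fb <- fitBiphasicInhibition(bip$dose, bip$speed)
  expect_equal(predictDose(fb, 0)$fit,
               unname(fitParams(fb)["y0"] + fitParams(fb)["yM"]))
})

test_that("biphasic fits keep K1 below K2 regardless of labelling", {
  doses <- c(0, 0.5, 1, 2.5, 5, 10, 25, 50, 100, 200)
  # the same curve written with swapped site labels
  d <- generateDoseResponse("biphasic",
                            list(y0 = 1, yM = 4, f1 = 0.4, K1 = 50, K2 = 2),
                            doses)
  f <- fitBiphasicInhibition(d$dose, d$speed)
  p <- fitParams(f)
  expect_lt(p["K1"], p["K2"])
  expect_equal(unname(p), c(1, 4, 0.6, 2, 50), tolerance = 1e-3)
})

test_that("parameter recovery is accurate and calibrated under noise", {
  doses <- c(0, 0.5, 1, 2.5, 5, 10, 25, 50, 100, 200)
  truth <- c(y0 = 1, yM = 5, K = 10)
  rng <- 4  # dynamic range of the noiseless curve
  relErr <- matrix(NA_real_, 40, 3)
  cover <- 0
  for (s in 1:40) {
    d <- generateDoseResponse("michaelian_inh", as.list(truth), doses,
                              noiseSd = 0.05 * rng, seed = s)
    f <- fitMichaelianInhibition(d$dose, d$speed)
    relErr[s, ] <- abs(fitParams(f) - truth) / truth
    se <- sqrt(diag(f@cov))
    if (all(abs(fitParams(f) - truth) <= 1.96 * se)) cover <- cover + 1
  }
  expect_lt(stats::median(relErr), 0.10)
  expect_gte(cover / 40, 0.8)  # joint coverage of all three intervals
})

test_that("degenerate dose designs are refused", {
  expect_error(fitMichaelianInhibition(c(0, 1, 2), c(1, 2, 3)), "4 distinct")
  expect_error(fitMichaelianInhibition(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "zero-dose")
  expect_error(fitBiphasicInhibition(c(0, 1, 2, 3, 4), c(5, 4, 3, 2, 1)),
               "6 distinct")
})

test_that("logistic gap fit recovers x50 within its confidence interval", {
  set.seed(1)
  w <- stats::runif(120, 35, 380)
  y <- stats::rbinom(120, 1, stats::plogis(0.05 * (160 - w)))
  f <- fitLogisticGap(w, y)
  expect_false(f@separated)
  expect_lt(f@beta1, 0)  # crossing probability decreases with gap width
  expect_lt(abs(f@x50 - 160), 1.96 * f@x50se)
})

test_that("complete separation is flagged and kept finite", {
  w <- c(50, 80, 120, 200, 260, 300)
  expect_warning(f <- fitLogisticGap(w, rep(1, 6)), "separated")
  expect_true(f@separated)
  expect_true(all(is.finite(c(f@beta0, f@beta1))))
  f2 <- suppressWarnings(fitLogisticGap(w, as.numeric(w < 150)))
  expect_true(f2@separated)
  expect_lt(f2@beta1, 0)
  expect_gt(f2@x50, 100); expect_lt(f2@x50, 230)
})

test_that("diffusion distance follows the square-root law", {
  expect_equal(diffusionDistance(200, 1), 20)
  expect_equal(diffusionDistance(10, 0), 0)
  expect_error(diffusionDistance(-1, 1), "nonnegative")
  # beyond the crossover a 5.5 µm/min wave outruns calcium diffusion
  tmin <- seq(1, 2880, by = 1)
  wave <- 5.5 * tmin
  diffu <- diffusionDistance(200, tmin * 60)
  cross <- which(wave > diffu)[1]
  expect_true(is.finite(cross))
  expect_true(all(wave[cross:length(tmin)] > diffu[cross:length(tmin)]))
  expect_true(all(wave[seq_len(max(1, cross - 2))] <=
                    diffu[seq_len(max(1, cross - 2))]))
})
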