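test_that("chi-square objective obeys its weighting laws", {
  m <- presetModels()[["6803-like"]]
  # a curve generated exactly by the model (no noise beyond sigma bookkeeping)
  q <- defaultQGrid(80)
  iModel <- modelIntensity(q, m, ResolutionSpec(sigmaQ = 0.05 * q))
  exact <- ScatteringCurve(q = q, intensity = iModel, sigmaI = 0.03 * iModel,
                           sigmaQ = 0.05 * q)
  prob <- fitProblem(exact)
  truth <- c(scale = 1, D = m@stack@D, N = m@stack@N, etaCP = m@stack@etaCP,
             dL = m@geometry@dL, dT = m@geometry@dT,
             rhoL = m@contrasts@rhoL, sigmaL = 0, B = 0, C = 0, n = 2)
  pt <- prob@start
  pt[names(truth)] <- truth
  expect_equal(chiSquare(prob, pt), 0, tolerance = 1e-10)

  # doubling all sigma_I divides chi-square by 4
  noisy <- generateCurve(m, seed = 3, q = q)
  p1 <- fitProblem(noisy)
  wide <- ScatteringCurve(q = q, intensity = intensities(noisy),
                          sigmaI = 2 * intensityError(noisy),
                          sigmaQ = qResolution(noisy))
  p2 <- fitProblem(wide)
  expect_equal(chiSquare(p2, pt), chiSquare(p1, pt) / 4, tolerance = 1e-12)
})

test_that("chi-square at truth is distributed around the point count", {
  # unit-sigma Gaussian noise on n points: E[chisq] = n
  m <- presetModels()[["6803-like"]]
  q <- defaultQGrid(100)
  iModel <- modelIntensity(q, m, ResolutionSpec(sigmaQ = 0.05 * q))
  truth <- c(scale = 1, D = m@stack@D, N = m@stack@N, etaCP = m@stack@etaCP,
             dL = m@geometry@dL, dT = m@geometry@dT,
             rhoL = m@contrasts@rhoL, sigmaL = 0, B = 0, C = 0, n = 2)
  set.seed(99)
  chis <- vapply(1:50, function(i) {
    cur <- ScatteringCurve(q = q,
                           intensity = iModel + rnorm(100, sd = 0.03 * iModel),
                           sigmaI = 0.03 * iModel, sigmaQ = 0.05 * q)
    prob <- fitProblem(cur)
    pt <- prob@start
    pt[names(truth)] <- truth
    chiSquare(prob, pt)
  }, numeric(1))
  # mean chisq ~ n with standard error sqrt(2n/50)
  expect_lt(abs(mean(chis) - 100), 3 * sqrt(2 * 100 / 50))
})

test_that("staged fit recovers ground truth from a near-noiseless curve", {
  m <- presetModels()[["7002-like"]]
  curve <- generateCurve(m, seed = 5, noiseRel = 1e-6)
  fit <- stagedFit(fitProblem(curve))
  p <- bestFit(fit)
  expect_lt(abs(p[["D"]] / m@stack@D - 1), 0.01)
  expect_lt(abs(p[["dL"]] / m@geometry@dL - 1), 0.05)
  expect_lt(abs(p[["dT"]] / m@geometry@dT - 1), 0.05)
  # deduced quantities are propagated
  ded <- deducedQuantities(fit)
  expect_equal(ded$dTM, 2 * p[["dT"]])
  expect_true(ded$peaksFound)
  expect_true(ded$identifiable)
  # the objective never increases across accepted stages
  expect_true(all(diff(fit@trace$chisq) <= 1e-9))
})

test_that("fits are bit-reproducible for identical inputs", {
  m <- presetModels()[["6803-like"]]
  curve <- generateCurve(m, seed = 8)
  f1 <- stagedFit(fitProblem(curve))
  f2 <- stagedFit(fitProblem(curve))
  expect_identical(bestFit(f1), bestFit(f2))
  expect_identical(chiSquareValue(f1), chiSquareValue(f2))
})

test_that("pure background data are flagged unidentifiable", {
  q <- defaultQGrid(120)
  i <- 0.3 + 2e-4 * q^-2
  set.seed(17)
  cur <- ScatteringCurve(q = q, intensity = i + rnorm(120, sd = 0.03 * i),
                         sigmaI = 0.03 * i)
  prob <- fitProblem(cur)
  warns <- character(0)
  fit <- withCallingHandlers(stagedFit(prob), warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  expect_true(any(grepl("no peak cluster", warns)))
  expect_true(any(grepl("unidentifiable", warns)))
  expect_false(deducedQuantities(fit)$identifiable)
})

test_that("profile likelihood matches curvature on a quadratic surface", {
  # chi-square is exactly quadratic in the overall scale when every other
  # parameter is fixed, so the delta-chisq = 1 interval must match the
  # curvature-based standard deviation
  m <- presetModels()[["6803-like"]]
  curve <- generateCurve(m, seed = 23)
  truth <- curveMetadata(curve)$groundTruth
  prob <- fitProblem(curve, start = as.list(truth),
                     fixed = setdiff(c("scale", "D", "N", "etaCP", "dL", "dT",
                                       "rhoL", "sigmaL", "B", "C", "n"),
                                     "scale"))
  fit <- stagedFit(prob, gridN = truth[["N"]], gridEta = truth[["etaCP"]])
  iv <- profileLikelihood(prob, fit, "scale")
  s <- bestFit(fit)[["scale"]]
  expect_true(iv[["lower"]] <= s && s <= iv[["upper"]])
  # curvature sigma from finite differences of the 1-parameter chi-square
  h <- 1e-4 * s
  pp <- bestFit(fit)
  chi <- function(v) { pp[["scale"]] <- v; chiSquare(prob, pp) }
  curv <- (chi(s + h) - 2 * chi(s) + chi(s - h)) / h^2
  sigma <- sqrt(2 / curv)
  expect_equal(unname(iv[["upper"]] - iv[["lower"]]), 2 * sigma,
               tolerance = 0.05)
})

test_that("profiling a fixed parameter returns a degenerate interval", {
  m <- presetModels()[["6803-like"]]
  curve <- generateCurve(m, seed = 2)
  prob <- fitProblem(curve)  # sigmaL fixed by default
  fakeFit <- new("FitResult", par = prob@start, fixed = prob@fixed,
                 lower = prob@lower, upper = prob@upper, chisq = 1,
                 redChisq = 1, nobs = 200L,
                 intervals = matrix(numeric(0), 0, 2),
                 deduced = list(), trace = data.frame(), curve = curve,
                 fittedIntensity = intensities(curve))
  iv <- profileLikelihood(prob, fakeFit, "sigmaL")
  expect_equal(unname(iv), c(0, 0))
})
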