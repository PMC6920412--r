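test_that("gaussian grid is normalized, symmetric and handles truncation", {
  g0 <- gaussianGrid(60, 0)
  expect_equal(g0$value, 60)
  expect_equal(g0$weight, 1)

  g <- gaussianGrid(60, 10, nQuad = 21, cutoff = 3)
  expect_equal(sum(g$weight), 1, tolerance = 1e-12)
  expect_equal(sum(g$value * g$weight), 60, tolerance = 1e-6)
  expect_equal(range(g$value), c(30, 90))

  # invalid (non-positive) values dropped before renormalization
  gt <- gaussianGrid(10, 10, nQuad = 21, cutoff = 3, lower = 0)
  expect_true(all(gt$value > 0))
  expect_equal(sum(gt$weight), 1, tolerance = 1e-12)
  expect_error(gaussianGrid(-50, 1, lower = 0), "invalid")
})

test_that("polydisperse intensity reduces to the monodisperse model", {
  geom <- refGeometry(); con <- refContrasts()
  sp <- StackParams(650, 4, 0.01)
  bg <- BackgroundParams(0.2, 1e-5, 2)
  q <- seq(0.006, 0.29, length.out = 60)
  mono <- polydisperseIntensity(q, geom, con, sp, bg, scale = 2,
                                poly = PolydispersitySpec(0, 0))
  expect_equal(mono, lamellarIntensity(q, geom, con, sp, bg, scale = 2),
               tolerance = 1e-12)
})

test_that("split-sum factorization matches the full double sum", {
  geom <- refGeometry(); con <- refContrasts()
  sp <- StackParams(650, 4, 0.005)
  bg <- BackgroundParams(0, 0, 2)
  q <- seq(0.006, 0.29, length.out = 80)
  poly <- PolydispersitySpec(sigmaL = 12, sigmaD = 30)
  split <- polydisperseIntensity(q, geom, con, sp, bg, poly = poly)
  full <- polydisperseIntensity(q, geom, con, sp, bg, poly = poly,
                                method = "double")
  expect_true(all(abs(split / full - 1) < 0.005))
})

test_that("lumen polydispersity fills in the deep form-factor minimum", {
  m <- presetModels()[["6803-like"]]
  q <- seq(0.01, 0.03, length.out = 300)
  mono <- polydisperseIntensity(q, m@geometry, m@contrasts, m@stack,
                                BackgroundParams(0, 0, 2),
                                poly = PolydispersitySpec(0, 0))
  qMin <- q[which.min(mono)]
  depths <- vapply(c(0, 5, 10, 15, 20), function(sL) {
    polydisperseIntensity(qMin, m@geometry, m@contrasts, m@stack,
                          BackgroundParams(0, 0, 2),
                          poly = PolydispersitySpec(sigmaL = sL, sigmaD = 0))
  }, numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("repeat-distance polydispersity damps high q like the Caille term", {
  m <- presetModels()[["6803-like"]]
  q <- seq(0.05, 0.29, length.out = 120)
  bg <- BackgroundParams(0, 0, 2)
  base <- polydisperseIntensity(q, m@geometry, m@contrasts,
                                StackParams(m@stack@D, 4, 0), bg,
                                poly = PolydispersitySpec(0, 0))
  viaSigmaD <- polydisperseIntensity(q, m@geometry, m@contrasts,
                                     StackParams(m@stack@D, 4, 0), bg,
                                     poly = PolydispersitySpec(0, 40))
  viaEta <- polydisperseIntensity(q, m@geometry, m@contrasts,
                                  StackParams(m@stack@D, 4, 0.03), bg,
                                  poly = PolydispersitySpec(0, 0))
  # both mechanisms damp the structure-factor features the same way:
  # rank correlation of the two damping ratios is strongly positive
  rd <- viaSigmaD / base
  re <- viaEta / base
  expect_gt(cor(rd, re, method = "spearman"), 0.8)
})

test_that("weighted sums are invariant to grid-point reordering", {
  # reordering enters via the grid construction; permuting the (value,
  # weight) pairs by hand must give the same weighted mean
  g <- gaussianGrid(60, 10, nQuad = 21, cutoff = 3)
  f <- function(x) sin(x / 7) + x^2 / 100
  set.seed(3)
  perm <- sample(nrow(g))
  expect_equal(sum(g$weight * f(g$value)),
               sum(g$weight[perm] * f(g$value[perm])), tolerance = 1e-14)
})

test_that("resolution smearing honors its exact limits", {
  m <- presetModels()[["6803-like"]]
  q <- seq(0.006, 0.29, length.out = 60)
  fn <- function(qq) polydisperseIntensity(
    qq, m@geometry, m@contrasts, m@stack, m@background, scale = 1,
    poly = m@poly)

  # sigmaQ = 0 returns the model unchanged
  expect_identical(resolutionSmear(fn, q, ResolutionSpec(sigmaQ = 0)), fn(q))

  # a constant model is invariant under smearing
  expect_equal(resolutionSmear(function(qq) rep(7, length(qq)), q,
                               ResolutionSpec(sigmaQ = 0.05 * q)),
               rep(7, length(q)), tolerance = 1e-12)

  # mixed zero/non-zero sigmaQ: zero rows exactly unsmeared
  sq <- 0.05 * q; sq[1:10] <- 0
  sm <- resolutionSmear(fn, q, ResolutionSpec(sigmaQ = sq))
  expect_identical(sm[1:10], fn(q[1:10]))
  expect_false(all(sm[11:60] == fn(q[11:60])))
})

test_that("smearing a Gaussian peak widens it in quadrature", {
  w <- 0.004
  q0 <- 0.1
  peak <- function(q) exp(-(q - q0)^2 / (2 * w^2))
  sq <- 0.003
  q <- seq(0.06, 0.14, length.out = 2001)
  sm <- resolutionSmear(peak, q, ResolutionSpec(sigmaQ = sq, nQuad = 41L,
                                                cutoff = 4))
  # measure the smeared width from second moments
  mu <- sum(q * sm) / sum(sm)
  sd <- sqrt(sum((q - mu)^2 * sm) / sum(sm))
  expect_equal(sd, sqrt(w^2 + sq^2), tolerance = 0.02)
  # the integral of the compactly supported peak is conserved
  expect_equal(sum(sm) * diff(q)[1], sum(peak(q)) * diff(q)[1],
               tolerance = 1e-3)
})
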