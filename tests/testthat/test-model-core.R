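test_that("boundary distances follow the box geometry", {
  bnd <- boundaries(BilayerGeometry(dH = 5, dT = 15, dL = 60))
  expect_equal(unname(bnd), c(70, 65, 35, 30))

  # head width zero collapses the head boundaries (single-box membrane mode)
  t <- 13; l <- 80
  bnd0 <- boundaries(BilayerGeometry(dH = 0, dT = t, dL = l))
  expect_equal(bnd0[["a"]], bnd0[["b"]])
  expect_equal(bnd0[["c"]], bnd0[["d"]])
  expect_equal(bnd0[["a"]], l / 2 + 2 * t)
  expect_equal(bnd0[["d"]], l / 2)

  # algebraic identities on random geometries
  set.seed(42)
  for (i in 1:20) {
    g <- randomGeometry()
    bnd <- boundaries(g)
    expect_equal(bnd[["a"]] - bnd[["b"]], g@dH)
    expect_equal(bnd[["b"]] - bnd[["c"]], 2 * g@dT)
    expect_equal(bnd[["c"]] - bnd[["d"]], g@dH)
    expect_true(all(diff(unname(bnd)) < 0) && bnd[["d"]] > 0)
  }

  # the printed-variant convention differs in c only
  g <- refGeometry()
  expect_equal(boundaries(g, "printed")[["c"]], g@dL + g@dH)
  expect_equal(boundaries(g, "printed")[c("a", "b", "d")],
               boundaries(g)[c("a", "b", "d")])

  expect_error(BilayerGeometry(dH = 1, dT = -2, dL = 50), "dT")
})

test_that("box amplitude matches its closed form and limits", {
  expect_equal(boxAmplitude(1e-12, delta = 10, deltaRho = 1), 20)
  expect_equal(boxAmplitude(pi / 10, delta = 10), 0, tolerance = 1e-12)
  expect_equal(boxAmplitude(0.1, delta = 10), 2 * sin(1) / 0.1,
               tolerance = 1e-12)
})

test_that("form factor equals the quadrature oracle and honors limits", {
  geom <- refGeometry()
  con <- refContrasts()

  # zero contrast gives zero everywhere
  zero <- ContrastProfile(0, 0, 0)
  expect_equal(doubleBilayerFormFactor(c(0.01, 0.1), geom, zero), c(0, 0))

  # q -> 0 limit: first-order sine expansion
  lim <- 4 * (2 * geom@dH * con@rhoH + 2 * geom@dT * con@rhoT +
                geom@dL / 2 * con@rhoL)^2
  expect_equal(doubleBilayerFormFactor(1e-6, geom, con), lim,
               tolerance = 1e-6)

  # quadrature oracle on random geometries and contrasts
  set.seed(7)
  for (i in 1:5) {
    g <- randomGeometry()
    cp <- randomContrasts()
    q <- sort(runif(50, 0.005, 0.3))
    expect_equal(doubleBilayerFormFactor(q, g, cp),
                 formFactorQuadrature(q, g, cp), tolerance = 1e-6)
  }

  # non-negativity over randomized parameters
  set.seed(8)
  for (i in 1:10) {
    q <- sort(runif(100, 1e-4, 0.5))
    expect_true(all(doubleBilayerFormFactor(q, randomGeometry(),
                                            randomContrasts()) >= 0))
  }
})

test_that("Caille exponent follows its closed form", {
  expect_equal(cailleAlpha(1:5, 0), rep(0, 5))
  expect_equal(cailleAlpha(1, 0.1),
               0.1 / (4 * pi^2) * (log(pi) + 0.5772156649),
               tolerance = 1e-10)
  a <- cailleAlpha(1:10, 0.05)
  expect_true(all(diff(a) > 0))
  expect_error(cailleAlpha(0, 0.1), "n")
})

test_that("structure factor limits, positivity and fractional N", {
  q <- seq(0.005, 0.3, length.out = 100)
  # N = 1: no interference
  expect_equal(structureFactor(q, StackParams(600, 1, 0.05)), rep(1, 100))
  # N = 2, rigid: 1 + cos(qD)
  expect_equal(structureFactor(q, StackParams(600, 2, 0)), 1 + cos(q * 600),
               tolerance = 1e-12)
  # Bragg positions at eta = 0 telescope to N, and S(q -> 0) = N
  for (N in 2:6) {
    sp <- StackParams(677.8, N, 0)
    qB <- 2 * pi * (1:4) / sp@D
    expect_equal(structureFactor(qB, sp), rep(N, 4), tolerance = 1e-10)
    expect_equal(structureFactor(1e-12, sp), N, tolerance = 1e-10)
  }
  # positivity over randomized parameters
  set.seed(9)
  for (i in 1:10) {
    sp <- StackParams(runif(1, 450, 950), sample(2:6, 1), runif(1, 0, 0.2))
    expect_true(all(structureFactor(q, sp) > 0))
  }
  # fractional N interpolates between the bracketing integers
  s4 <- structureFactor(q, StackParams(600, 4, 0.01))
  s5 <- structureFactor(q, StackParams(600, 5, 0.01))
  s43 <- structureFactor(q, StackParams(600, 4.3, 0.01))
  expect_equal(s43, 0.7 * s4 + 0.3 * s5, tolerance = 1e-12)
})

test_that("lamellar intensity combines P, S and background linearly", {
  geom <- refGeometry(); con <- refContrasts()
  q <- seq(0.006, 0.29, length.out = 80)
  sp1 <- StackParams(650, 1, 0)
  bg0 <- BackgroundParams(0, 0, 2)

  # N = 1: I proportional to P / q^2
  i1 <- lamellarIntensity(q, geom, con, sp1, bg0, scale = 1)
  p <- doubleBilayerFormFactor(q, geom, con)
  expect_equal(i1, 2 * pi * p / (650 * q^2), tolerance = 1e-12)

  # doubling the scale doubles I - Ib at every q
  bg <- BackgroundParams(B = 0.5, C = 1e-4, n = 2)
  sp <- StackParams(650, 4, 0.01)
  iA <- lamellarIntensity(q, geom, con, sp, bg, scale = 1)
  iB <- lamellarIntensity(q, geom, con, sp, bg, scale = 2)
  ib <- backgroundIntensity(q, bg)
  expect_equal(iB - ib, 2 * (iA - ib), tolerance = 1e-9)

  expect_error(lamellarIntensity(c(0, 0.1), geom, con, sp), "q")
})

test_that("Bragg peaks sit at 2*pi*n/D for a rigid well-ordered stack", {
  # a rigid N = 6 stack shows maxima at the first four Bragg orders, each
  # within a few percent of the order spacing; residual displacement is the
  # form-factor modulation, largest where P(q) has its deep minimum
  m <- presetModels()[["6803-like"]]
  D <- m@stack@D
  sp <- StackParams(D, 6, 0)
  q <- seq(0.006, 0.05, length.out = 4000)
  i <- lamellarIntensity(q, m@geometry, m@contrasts, sp,
                         BackgroundParams(0, 0, 2), 1)
  for (n in 1:4) {
    qB <- 2 * pi * n / D
    win <- which(abs(q - qB) < 0.35 * 2 * pi / D)
    pk <- win[which.max(i[win])]
    expect_lt(abs(q[pk] - qB), 0.05 * 2 * pi / D)
    expect_true(pk > min(win) && pk < max(win))  # a true interior maximum
  }
})

test_that("raising the Caille parameter damps the third-order peak", {
  m <- presetModels()[["6803-like"]]
  q3 <- 2 * pi * 3 / m@stack@D
  heights <- vapply(c(0, 0.005, 0.02, 0.05, 0.1), function(eta) {
    lamellarIntensity(q3, m@geometry, m@contrasts,
                      StackParams(m@stack@D, 4, eta),
                      BackgroundParams(0, 0, 2), 1)
  }, numeric(1))
  expect_true(all(diff(heights) < 0))
})
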