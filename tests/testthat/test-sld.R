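test_that("mixture and water SLDs are volume-weighted sums", {
  expect_equal(mixtureSLD(5.2, 1), 5.2)
  expect_equal(mixtureSLD(c(3, -3), c(0.5, 0.5)), 0)
  # 90/10 D2O/H2O against hand computation
  tab <- defaultSLDTable()
  expect_equal(waterSLD(tab, 0.9), 0.9 * 6.36 + 0.1 * (-0.56),
               tolerance = 1e-12)
  expect_error(mixtureSLD(c(1, 2), c(0.5, 0.6)), "sum to 1")
})

test_that("single-box membrane SLD averages tail and head regions", {
  # the worked neutron computation: protein-averaged inputs in 1e-6 1/A^2
  expect_equal(membraneSLD(1.832, 1.327), 1.5795, tolerance = 1e-12)
  expect_equal(round(membraneSLD(1.832, 1.327), 2), 1.58)
  # average of equals is itself
  expect_equal(membraneSLD(2.2, 2.2), 2.2)
  # protein fraction 0 gives the pure-lipid average
  tab <- defaultSLDTable()
  expect_equal(membraneSLDFromTable(tab, proteinFraction = 0),
               0.5 * (-0.39 + 1.86), tolerance = 1e-12)
  # protein-averaged region SLD interpolates protein and lipid
  expect_equal(proteinAveragedSLD(tab, "tail", 0.7),
               0.7 * 2.78 + 0.3 * (-0.39), tolerance = 1e-12)
})

test_that("protein SLD interpolates the labile H-D exchange level", {
  tab <- defaultSLDTable()
  s0 <- proteinSLD(tab, "phycobilisome", "neutron", 0)
  s1 <- proteinSLD(tab, "phycobilisome", "neutron", 1)
  expect_equal(proteinSLD(tab, "phycobilisome", "neutron", 0.5),
               (s0 + s1) / 2)
  # X-ray values do not depend on exchange
  expect_equal(proteinSLD(tab, "phycobilisome", "xray", 0.9),
               proteinSLD(tab, "phycobilisome", "xray", 0))
  expect_error(proteinSLD(tab, "unobtainium"), "no unique entry")
})

test_that("relative contrast map anchors membrane at -1 and inverts exactly", {
  expect_equal(toRelative(3.61, sldIT = 3.61, sldTM = 1.58), 0)
  expect_equal(toRelative(1.58, sldIT = 3.61, sldTM = 1.58), -1)
  # round trip on random values, both orderings of TM vs IT
  set.seed(21)
  for (i in 1:20) {
    it <- runif(1, -1, 12); tm <- runif(1, -1, 12)
    if (abs(tm - it) < 0.1) next
    x <- runif(1, -5, 15)
    expect_equal(fromRelative(toRelative(x, it, tm), it, tm), x,
                 tolerance = 1e-12)
    expect_equal(toRelative(tm, it, tm), -1)
  }
})

test_that("deduced parameters reproduce the worked strain values", {
  d1 <- deducedParameters(D = 677.8, dL = 62.13, dT = 16.89)
  expect_equal(d1$dIT, 548.11, tolerance = 0.1)
  d2 <- deducedParameters(D = 597.6, dL = 84.66, dT = 20.90)
  expect_equal(d2$dIT, 429.34, tolerance = 0.1)
  expect_equal(d1$dTM, 33.78)
  expect_true(d1$physical)
  expect_warning(dBad <- deducedParameters(D = 100, dL = 84, dT = 20),
                 "unphysical")
  expect_false(dBad$physical)
})

test_that("scenario solver algebra matches the two-component rearrangement", {
  tab <- defaultSLDTable()
  # lumen SLD equal to pure solvent implies zero protein from X-rays
  watX <- waterSLD(tab, 1, "xray")
  plcX <- proteinSLD(tab, "plastocyanin", "xray")
  expect_equal((watX - watX) / (plcX - watX), 0)
  # random two-component solves invert mixtureSLD
  set.seed(31)
  for (i in 1:20) {
    phi <- runif(1)
    sldL <- mixtureSLD(c(plcX, watX), c(phi, 1 - phi))
    expect_equal((sldL - watX) / (plcX - watX), phi, tolerance = 1e-12)
  }
})

test_that("scenario search is ranked, constrained and grid-order invariant", {
  ranked <- scenarioSearch()
  expect_gt(nrow(ranked), 0)
  expect_true(all(diff(ranked$score) >= 0))
  phis <- c(ranked$phiLumenProteinN, ranked$phiLumenProteinX,
            ranked$phiPhyco)
  expect_true(all(phis >= 0 & phis <= 1))
  expect_true(all(ranked$fD2OPrime <= ranked$fD2O + 1e-12))

  # reordering the input grids leaves the ranking unchanged
  rankedRev <- scenarioSearch(phiPhycoGrid = rev(seq(0.60, 0.85, by = 0.05)),
                              wGrid = rev(seq(0, 0.9, by = 0.1)))
  expect_equal(ranked[order(ranked$phiPhyco, ranked$wExchange, ranked$fD2O), ],
               rankedRev[order(rankedRev$phiPhyco, rankedRev$wExchange,
                               rankedRev$fD2O), ],
               tolerance = 1e-12, ignore_attr = TRUE)

  # near-optimal stability under grid refinement: halving the step sizes
  # keeps the coarse winner essentially optimal (the score landscape is
  # nearly degenerate among consistent scenarios, so the solver reports the
  # full ranked table rather than a single winner)
  fine <- scenarioSearch(phiPhycoGrid = seq(0.60, 0.85, by = 0.025),
                         wGrid = seq(0, 0.9, by = 0.05))
  expect_lte(fine$score[1], ranked$score[1])
  expect_lt(ranked$score[1] - fine$score[1], 0.005)
  coarseWinner <- fine[fine$phiPhyco == ranked$phiPhyco[1] &
                         fine$wExchange == ranked$wExchange[1] &
                         fine$fD2O == ranked$fD2O[1], ]
  expect_equal(coarseWinner$score, ranked$score[1], tolerance = 1e-12)

  # impossible contrasts yield an empty, diagnosable result
  expect_message(none <- scenarioSearch(contrastN = 50, contrastX = 50),
                 "no scenario")
  expect_equal(nrow(none), 0)
})

test_that("SLD tables round-trip through their columnar text format", {
  tab <- defaultSLDTable()
  path <- tempfile(fileext = ".txt")
  writeSLDTable(tab, path)
  back <- readSLDTable(path)
  expect_equal(back, tab, ignore_attr = TRUE)
})
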