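identityCurve <- function(span = 8000, sigma = 1e-4) {
  calCurve(0:span, 0:span, rep(sigma, span + 1))
}

test_that("identity-curve calibration reproduces the input Gaussian", {
  crv <- identityCurve()
  d <- calibrate(5000, 50, crv)
  expect_lt(abs(pointEstimate(d, "median") - 5000), 1)
  expect_lt(abs(pointEstimate(d, "mean") - 5000), 1)
  expect_lt(abs(pointEstimate(d, "mode") - 5000), 1)
  # density matches the Gaussian cell-wise
  ref <- dnorm(calAges(d), 5000, 50)
  expect_lt(max(abs(densityMass(d) - ref / sum(ref))), 1e-12)
})

test_that("piecewise-linear curve median matches the fine-grid oracle", {
  # two segments with different slopes
  crv <- calCurve(c(0, 1000, 3000), c(0, 800, 3400), c(10, 10, 10))
  d <- calibrate(1000, 30, crv)
  expect_lt(abs(pointEstimate(d, "median") -
    calibrateOracle(1000, 30, crv)), 1)
  d2 <- calibrate(2500, 40, crv)
  expect_lt(abs(pointEstimate(d2, "median") -
    calibrateOracle(2500, 40, crv)), 1)
})

test_that("a plateau yields a multimodal density with split HPD", {
  crv <- genCalCurve(6000, wiggleAmplitude = 40, seed = 2, plateau = TRUE)
  plateauC14 <- c14Ages(crv)[which(calAges(crv) >= 0.425 * 6000)[1]]
  d <- calibrate(plateauC14, 10, crv)
  h <- hpdInterval(d, 0.95)
  expect_gte(nrow(h), 2)
  expect_gte(attr(h, "totalMass"), 0.95)
})

test_that("determinations outside the curve range are rejected", {
  crv <- identityCurve(2000)
  expect_error(calibrate(5000, 50, crv), "range")
  expect_s4_class(calibrate(2100, 50, crv), "CalDensity")  # within 10 sigma
})

test_that("HPD picks the smallest cell set and splits correctly", {
  d3 <- calDensity(c(1, 2, 3), c(0.5, 0.3, 0.2))
  h <- hpdInterval(d3, 0.8)
  expect_equal(nrow(h), 1)
  expect_equal(h$lower, 1)
  expect_equal(h$upper, 2)

  # symmetric unimodal: one interval symmetric about the mode
  g <- seq(-50, 50)
  ds <- calDensity(g + 100, dnorm(g, 0, 10))
  hs <- hpdInterval(ds, 0.9)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$lower - 100, -(hs$upper - 100))

  # bimodal mixture vs the smallest-cell-count oracle on a 50-cell grid
  g50 <- seq_len(50)
  m <- dnorm(g50, 15, 3) + dnorm(g50, 38, 4)
  db <- calDensity(g50, m)
  hb <- hpdInterval(db, 0.95)
  cells <- unlist(lapply(seq_len(nrow(hb)), function(i)
    which(g50 >= hb$lower[i] & g50 <= hb$upper[i])))
  expect_equal(sort(cells), hpdOracleCells(densityMass(db), 0.95))
  expect_equal(nrow(hb), 2)
})

test_that("point estimates follow their definitions", {
  d <- calDensity(c(10, 20), c(0.6, 0.4))
  expect_equal(pointEstimate(d, "median"), 10)
  expect_equal(pointEstimate(d, "mean"), 14)
  expect_equal(pointEstimate(d, "mode"), 10)
  # mode tie resolves to the older age
  dt <- calDensity(c(10, 20), c(0.5, 0.5))
  expect_equal(pointEstimate(dt, "mode"), 20)

  set.seed(7)
  m <- runif(100)
  dr <- calDensity(seq_len(100), m)
  mass <- m / sum(m)
  expect_equal(pointEstimate(dr, "median"),
    seq_len(100)[which(cumsum(mass) >= 0.5)[1]])
  expect_equal(pointEstimate(dr, "mean"), sum(seq_len(100) * mass))
  expect_equal(pointEstimate(dr, "mode"), which.max(mass))
})

test_that("calibration invariants hold", {
  crv <- genCalCurve(8000, wiggleAmplitude = 20, seed = 3)
  # normalization
  d <- calibrate(4000, 60, crv)
  expect_lt(abs(sum(densityMass(d)) - 1), 1e-9)
  # monotone curve: calibrated median monotone in c14 age
  meds <- vapply(seq(2000, 6000, by = 500), function(a)
    pointEstimate(calibrate(a, 50, crv), "median"), numeric(1))
  expect_true(all(diff(meds) > 0))
  # HPD nesting
  h50 <- hpdInterval(d, 0.5)
  h95 <- hpdInterval(d, 0.95)
  cellsOf <- function(h) unlist(lapply(seq_len(nrow(h)), function(i)
    which(calAges(d) >= h$lower[i] & calAges(d) <= h$upper[i])))
  expect_true(all(cellsOf(h50) %in% cellsOf(h95)))
  # grid refinement: halving the step moves the median by < step
  m1 <- pointEstimate(calibrate(4000, 60, crv, gridStep = 2), "median")
  m2 <- pointEstimate(calibrate(4000, 60, crv, gridStep = 1), "median")
  expect_lt(abs(m1 - m2), 2)
})

test_that("calibrateRecords reports medians and HPD bounds per record", {
  crv <- identityCurve(20000)
  r <- datedRecords(taxon = c("a", "a", "b"), age = c(12000, 12500, 13000),
    sigma = c(50, 60, 40), age_type = c("c14", "c14", "calibrated"))
  tab <- calibrateRecords(r, crv)
  expect_equal(nrow(tab), 3)
  expect_lt(abs(tab$median[1] - 12000), 1)
  expect_equal(tab$median[3], 13000)
  expect_lt(abs(tab$lower[3] - (13000 - 1.96 * 40)), 0.5)
})
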