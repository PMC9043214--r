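test_that("generators are pure functions of (parameters, seed)", {
  c1 <- genCalCurve(4000, 30, seed = 5)
  c2 <- genCalCurve(4000, 30, seed = 5)
  expect_identical(c14Ages(c1), c14Ages(c2))
  s1 <- genSightings(12000, 3000, 12, 60, seed = 5)
  s2 <- genSightings(12000, 3000, 12, 60, seed = 5)
  expect_identical(s1$series@age, s2$series@age)
  t1 <- genTrainingSet(nTaxa = 10, nSamples = 20, seed = 5)
  t2 <- genTrainingSet(nTaxa = 10, nSamples = 20, seed = 5)
  expect_identical(countMatrix(t1$counts), countMatrix(t2$counts))
  f1 <- genFossilSequence(c(10, 15), t1$truth, seed = 5)
  f2 <- genFossilSequence(c(10, 15), t2$truth, seed = 5)
  expect_identical(countMatrix(f1$counts), countMatrix(f2$counts))
  # different seeds differ
  expect_false(identical(s1$series@age,
    genSightings(12000, 3000, 12, 60, seed = 6)$series@age))
})

test_that("zero wiggle amplitude gives the identity curve", {
  crv <- genCalCurve(3000, wiggleAmplitude = 0, seed = 1)
  expect_equal(c14Ages(crv), calAges(crv))
})

test_that("excessive wiggle amplitude is rejected, plateaus are flat", {
  expect_error(genCalCurve(3000, wiggleAmplitude = 5000, seed = 1),
    "monotonicity")
  crv <- genCalCurve(6000, 40, seed = 2, plateau = TRUE)
  cal <- calAges(crv)
  d <- diff(c14Ages(crv))
  inPlateau <- cal >= 0.425 * 6000 & cal < 0.575 * 6000
  expect_true(any(d[inPlateau[-length(cal)]] < 0))  # ripple re-crosses
  expect_true(all(d[!inPlateau[-length(cal)]] > 0)) # monotone elsewhere
})

test_that("sighting series respect their recovery window", {
  g0 <- genSightings(12000, 4000, 50, datingSd = 0, seed = 3)
  expect_true(all(g0$series@age >= 12000))
  expect_true(all(g0$series@age <= 16000))
  # with many records the empirical minimum approaches the true extinction
  # with high probability (the gap beyond 100 yr has probability ~ exp(-4))
  gaps <- vapply(1:30, function(s)
    min(genSightings(12000, 5000, 200, datingSd = 0, seed = s)$series@age) -
      12000, numeric(1))
  expect_gte(mean(gaps < 100), 0.8)
  expect_lt(median(gaps), 50)
  # truth is serialized alongside
  expect_equal(g0$truth$trueExtinction, 12000)
  expect_length(g0$truth$trueAges, 50)
})

test_that("infinite tolerance removes the climate signal", {
  ts <- genTrainingSet(nTaxa = 8, nSamples = 120, tolerance = Inf,
    grainsPerSample = 500, seed = 7)
  m <- countMatrix(ts$counts)
  p <- m / rowSums(m)
  # every taxon's expected share is 1/8 regardless of climate; sample
  # correlations stay within binomial noise (|z| < 4 at n = 120)
  cors <- abs(apply(p, 2, cor, y = ts$climate))
  expect_lt(max(cors), 4 / sqrt(120))
  expect_lt(max(abs(colMeans(p) - 1 / 8)), 0.02)
})

test_that("WA optimum estimates recover the generator's truth", {
  ts <- genTrainingSet(nTaxa = 30, nSamples = 400, optimaRange = c(5, 25),
    tolerance = 2, grainsPerSample = 5000, seed = 9)
  m <- countMatrix(ts$counts)
  p <- m / rowSums(m)
  wa <- colSums(p * ts$climate) / colSums(p)
  w <- sweep(p, 2, colSums(p), "/")
  neff <- 1 / colSums(w^2)                   # effective samples per taxon
  se <- ts$truth$tolerance / sqrt(neff)
  interior <- ts$truth$optima > 9 & ts$truth$optima < 21
  z <- abs(wa - ts$truth$optima) / se
  expect_lt(max(z[interior]), 4)
})

test_that("fossil sequences carry their trajectory and warn on extrapolation", {
  ts <- genTrainingSet(nTaxa = 10, nSamples = 30, seed = 8)
  fo <- genFossilSequence(c(10, 12, 14), ts$truth, seed = 1,
    ages = c(15000, 14000, 13000))
  expect_equal(fo$truth$trajectory, c(10, 12, 14))
  expect_equal(sampleAges(fo$counts), c(15000, 14000, 13000))
  expect_warning(genFossilSequence(c(2, 30), ts$truth, seed = 1),
    "extrapolation")
})

test_that("generated data pass the readers after a write/read round trip", {
  dir <- withr::local_tempdir()
  crv <- genCalCurve(3000, 20, seed = 10)
  f1 <- file.path(dir, "curve.csv")
  writeCalCurve(crv, f1)
  expect_s4_class(readCalCurve(f1, "simple"), "CalCurve")
  ts <- genTrainingSet(nTaxa = 6, nSamples = 10, seed = 10)
  f2 <- file.path(dir, "counts.csv")
  writeCounts(ts$counts, f2)
  expect_equal(countMatrix(readCounts(f2)), countMatrix(ts$counts))
})
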