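test_that("chord distance matches hand calculation and vegan's Hellinger", {
  a <- c(25, 25, 50)
  b <- c(0, 50, 50)
  hand <- sqrt((sqrt(.25) - 0)^2 + (sqrt(.25) - sqrt(.5))^2 +
    (sqrt(.5) - sqrt(.5))^2)
  expect_equal(chordDistance(a, b), hand)
  expect_equal(chordDistance(a, b, "squared-chord"), hand^2)
  # cross-check: Euclidean distance of Hellinger-standardized rows
  m <- rbind(a, b)
  veg <- as.numeric(dist(vegan::decostand(m, "hellinger")))
  expect_equal(chordDistance(a, b), veg, tolerance = 1e-12)
})

test_that("chord distance is a metric on random compositions", {
  set.seed(17)
  for (r in 1:30) {
    x <- runif(6); y <- runif(6); z <- runif(6)
    expect_equal(chordDistance(x, y), chordDistance(y, x))
    expect_equal(chordDistance(x, x), 0)
    expect_lte(chordDistance(x, z),
      chordDistance(x, y) + chordDistance(y, z) + 1e-12)
  }
})

test_that("zero-distance analogues force an exact match", {
  ts <- genTrainingSet(nTaxa = 15, nSamples = 40, seed = 2)
  m <- countMatrix(ts$counts)
  out <- matReconstruct(ts$counts, ts$climate, m[3, , drop = FALSE], k = 5)
  expect_equal(out$estimate, unname(ts$climate[3]))
  expect_equal(out$minDist, 0)
})

test_that("the weighted mean over k analogues matches a hand calculation", {
  # 5 modern samples, 2 taxa; fossil closest to samples 1 and 2
  m <- matrix(c(
    90, 10,
    70, 30,
    50, 50,
    30, 70,
    10, 90), 5, 2, byrow = TRUE,
    dimnames = list(paste0("m", 1:5), c("A", "B")))
  clim <- c(10, 12, 15, 18, 20)
  fossil <- matrix(c(85, 15), 1, 2, dimnames = list("f", c("A", "B")))
  d <- apply(m, 1, function(r) chordDistance(fossil[1, ], r))
  sel <- order(d)[1:2]
  hand <- sum(clim[sel] / d[sel]) / sum(1 / d[sel])
  out <- matReconstruct(m, clim, fossil, k = 2)
  expect_equal(out$estimate, hand)
  expect_equal(out$nAnalogues, 2L)
})

test_that("analogues sharing a climate value dominate any weighting", {
  m <- matrix(c(80, 20, 60, 40, 20, 80), 3, 2, byrow = TRUE,
    dimnames = list(paste0("m", 1:3), c("A", "B")))
  fossil <- matrix(c(75, 25), 1, 2, dimnames = list("f", c("A", "B")))
  out <- matReconstruct(m, c(14, 14, 14), fossil, k = 3)
  expect_equal(out$estimate, 14)
})

test_that("the distance threshold drops bad analogues and can empty the set", {
  m <- matrix(c(90, 10, 85, 15, 10, 90), 3, 2, byrow = TRUE,
    dimnames = list(paste0("m", 1:3), c("A", "B")))
  clim <- c(10, 11, 20)
  fossil <- matrix(c(88, 12), 1, 2, dimnames = list("f", c("A", "B")))
  all3 <- matReconstruct(m, clim, fossil, k = 3)
  tight <- matReconstruct(m, clim, fossil, k = 3, threshold = 0.2)
  expect_lt(tight$estimate, all3$estimate)  # distant warm analogue dropped
  none <- matReconstruct(m, clim, fossil, k = 3, threshold = 1e-9)
  expect_true(is.na(none$estimate))
  expect_equal(none$flag, "no-analogue")
  # MAT estimates stay within the climate range of retained analogues
  expect_gte(all3$estimate, min(clim))
  expect_lte(all3$estimate, max(clim))
})

test_that("the Monte-Carlo threshold is seeded, monotone and recomputable", {
  ts <- genTrainingSet(nTaxa = 12, nSamples = 30, seed = 6)
  m <- countMatrix(ts$counts)
  # identical training samples give a zero threshold
  same <- m[rep(1, 5), ]
  rownames(same) <- paste0("r", 1:5)
  expect_equal(matThreshold(same, nPairs = 200, probs = 0.5, seed = 1), 0)
  # monotone non-decreasing in the quantile
  th <- vapply(c(0.05, 0.25, 0.5, 0.9),
    function(q) matThreshold(m, nPairs = 500, probs = q, seed = 2),
    numeric(1))
  expect_true(all(diff(th) >= 0))
  # direct recomputation with the same seed and pair protocol
  t1 <- matThreshold(m, nPairs = 1000, probs = 0.05, seed = 3)
  set.seed(3)
  n <- nrow(m)
  i <- sample.int(n, 1000, replace = TRUE)
  j <- vapply(i, function(a) {
    b <- sample.int(n - 1L, 1L)
    if (b >= a) b + 1L else b
  }, integer(1))
  d <- vapply(seq_along(i), function(r)
    chordDistance(m[i[r], ], m[j[r], ]), numeric(1))
  expect_equal(t1, unname(quantile(d, 0.05)), tolerance = 1e-12)
  expect_error(matThreshold(m[1, , drop = FALSE]), "at least 2")
})
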