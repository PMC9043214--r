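toyTraining <- function(n = 12, m = 6, seed = 21, grains = 400) {
  set.seed(seed)
  clim <- seq(6, 24, length.out = n)
  optima <- seq(7, 23, length.out = m)
  counts <- t(vapply(clim, function(x) {
    lam <- exp(-(x - optima)^2 / 8)
    as.integer(rmultinom(1, grains, lam / sum(lam)))
  }, integer(m)))
  dimnames(counts) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(m)))
  list(counts = counts, climate = clim)
}

test_that("component 1 equals two-way WA with inverse deshrinking", {
  tt <- toyTraining(n = 25, m = 8, seed = 2)
  for (sq in c(TRUE, FALSE)) {
    fit <- waplsFit(tt$counts, tt$climate, 2, sqrtTransform = sq)
    expect_lt(max(abs(fit@fitted[, 1] -
      waOracleFitted(tt$counts, tt$climate, sq))), 1e-8)
  }
})

test_that("a constant climate gives a constant 1-component fit and rejects more", {
  tt <- toyTraining()
  xconst <- rep(15, nrow(tt$counts))
  fit <- waplsFit(tt$counts, xconst, 1)
  expect_equal(unname(fit@fitted[, 1]), rep(15, nrow(tt$counts)))
  pr <- waplsPredict(fit, tt$counts, 1)
  expect_equal(pr$estimate, rep(15, nrow(tt$counts)))
  expect_error(waplsFit(tt$counts, xconst, 2), "degenerate")
})

test_that("zero-abundance taxa are dropped with a warning", {
  tt <- toyTraining()
  m <- cbind(tt$counts, ghost = 0L)
  expect_warning(fit <- waplsFit(m, tt$climate, 2), "ghost")
  expect_false("ghost" %in% fit@taxa)
})

test_that("predictions reproduce fitted values in-sample and flag no-overlap", {
  tt <- toyTraining()
  fit <- waplsFit(tt$counts, tt$climate, 3)
  for (k in 1:3) {
    pr <- waplsPredict(fit, tt$counts, k)
    expect_lt(max(abs(pr$estimate - fit@fitted[, k])), 1e-10)
  }
  # all-zero fossil row: missing estimate plus flag
  z <- matrix(0, 1, ncol(tt$counts),
    dimnames = list("empty", colnames(tt$counts)))
  przz <- waplsPredict(fit, z, 1)
  expect_true(is.na(przz$estimate))
  expect_equal(przz$flag, "no-overlap")
  # unmatched taxa are reported
  odd <- matrix(c(5, 3), 1, 2, dimnames = list("x", c("t1", "nota")))
  pro <- waplsPredict(fit, odd, 1)
  expect_equal(attr(pro, "droppedTaxa"), "nota")
})

test_that("leave-one-out equals a brute-force refit loop", {
  tt <- toyTraining(n = 12)
  cv <- looCrossvalidate(tt$counts, tt$climate, 2)
  manual <- matrix(NA_real_, 12, 2)
  for (i in 1:12) {
    f <- waplsFit(tt$counts[-i, ], tt$climate[-i], 2)
    for (k in 1:2)
      manual[i, k] <- waplsPredict(f, tt$counts[i, , drop = FALSE],
        k)$estimate
  }
  expect_lt(max(abs(cv@predicted - manual)), 1e-10)
  expect_lt(abs(cv@stats$rmsep[1] -
    sqrt(mean((manual[, 1] - tt$climate)^2))), 1e-10)
})

test_that("duplicating the training set deflates LOO error (leakage)", {
  tt <- toyTraining(n = 12)
  cv1 <- looCrossvalidate(tt$counts, tt$climate, 1)
  dup <- rbind(tt$counts, tt$counts)
  rownames(dup) <- paste0("s", seq_len(24))
  cv2 <- looCrossvalidate(dup, c(tt$climate, tt$climate), 1)
  expect_lt(cv2@stats$rmsep[1], cv1@stats$rmsep[1])
})

test_that("component selection follows the randomization t-test rules", {
  # forced rule: component 2 with RMSEP >= component 1 selects 1
  pred <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  obs <- c(1, 2, 3, 4)
  cv <- new("CvStatistics",
    stats = data.frame(component = 1:2,
      r2 = c(1, 1),
      rmsep = c(0, sqrt(mean((pred[, 2] - obs)^2))),
      maxBias = c(0, 1)),
    predicted = pred, observed = obs)
  expect_identical(as.integer(selectComponent(cv, 99, seed = 1)), 1L)
  # permutation p bounded in [1/(n+1), 1]
  p <- attr(selectComponent(cv, 99, seed = 1), "pValues")
  expect_true(all(p[!is.na(p)] >= 1 / 100 & p[!is.na(p)] <= 1))
  # structured benchmark: later components genuinely improve (seeded)
  ts <- genTrainingSet(seed = 1)
  cvb <- looCrossvalidate(ts$counts, ts$climate, 3)
  expect_lt(cvb@stats$rmsep[2], cvb@stats$rmsep[1])
  expect_gte(as.integer(selectComponent(cvb, 199, seed = 1)), 2L)
})

test_that("bootstrap errors are seeded, stable and shift-equivariant", {
  tt <- toyTraining(n = 50, m = 8, seed = 31)
  fossil <- tt$counts[c(5, 25, 45), ]
  b1 <- bootstrapErrors(tt$counts, tt$climate, fossil, component = 1,
    nCycles = 100, seed = 3)
  b2 <- bootstrapErrors(tt$counts, tt$climate, fossil, component = 1,
    nCycles = 100, seed = 3)
  expect_identical(b1$se, b2$se)
  b4 <- bootstrapErrors(tt$counts, tt$climate, fossil, component = 1,
    nCycles = 200, seed = 3)
  expect_true(all(abs(b4$se - b1$se) / b1$se < 0.10))
  # adding a constant to the climate shifts predictions, not errors
  b5 <- bootstrapErrors(tt$counts, tt$climate + 7, fossil, component = 1,
    nCycles = 100, seed = 3)
  expect_equal(b5$estimate, b1$estimate + 7, tolerance = 1e-9)
  expect_equal(b5$se, b1$se, tolerance = 1e-9)
})

test_that("reconstruction significance is bounded and detects a real gradient", {
  ts <- genTrainingSet(nTaxa = 20, nSamples = 60, seed = 4)
  traj <- seq(9, 21, length.out = 15)
  fo <- genFossilSequence(traj, ts$truth, seed = 5)
  p <- reconstructionSignificance(ts$counts, ts$climate, fo$counts,
    nRandomizations = 99, seed = 2, method = "mat")
  expect_equal(as.numeric(p), 1 / 100)
  expect_true(attr(p, "observed") > max(attr(p, "null")))
  # the permutation p is bounded in [1/(n+1), 1] whatever the method
  pw <- reconstructionSignificance(ts$counts, ts$climate, fo$counts,
    component = 1, nRandomizations = 19, seed = 2, method = "wapls")
  expect_gte(as.numeric(pw), 1 / 20)
  expect_lte(as.numeric(pw), 1)
  # genuinely driven sequence at the method's standard 999 randomizations
  p999 <- reconstructionSignificance(ts$counts, ts$climate, fo$counts,
    nRandomizations = 999, seed = 3, method = "mat")
  expect_equal(as.numeric(p999), 0.001)
})

test_that("the downcore trajectory is recovered on the benchmark", {
  ts <- genTrainingSet(seed = 1)
  fit <- waplsFit(ts$counts, ts$climate, 2)
  expect_gt(cor(fit@fitted[, 2], ts$climate)^2, 0.9)
  traj <- seq(8, 22, length.out = 30) +
    1.5 * sin(seq(0, 3 * pi, length.out = 30))
  fo <- genFossilSequence(traj, ts$truth, seed = 2)
  wp <- waplsPredict(fit, fo$counts, 2)
  expect_lt(sqrt(mean((wp$estimate - traj)^2)), 1.5)
  expect_gt(cor(wp$estimate, traj), 0.9)
})
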