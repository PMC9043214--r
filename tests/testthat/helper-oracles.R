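# Independent oracles used across the suite. Each recomputes the target
# quantity by a route different from the package implementation.

# Hand-stepped inverse-weighted McInerny terminal date (explicit loop).
griwmOracle <- function(ages, alpha = 0.05) {
  t <- sort(ages)
  n <- length(t)
  Ti <- wi <- numeric(n - 1)
  for (i in 2:n) {
    gap <- t[i] - t[1]
    lam <- (i - 1) / gap
    ext <- if (lam >= 1) 0 else log(alpha) / log(1 - lam)
    Ti[i - 1] <- t[1] - ext
    wi[i - 1] <- 1 / gap
  }
  sum(wi * Ti) / sum(wi)
}

# Fine-grid brute-force calibration: posterior median on a 0.1-yr grid.
calibrateOracle <- function(c14Age, sigma, curve, step = 0.1) {
  grid <- seq(min(calAges(curve)), max(calAges(curve)), by = step)
  mu <- approx(calAges(curve), c14Ages(curve), grid)$y
  s <- approx(calAges(curve), curveSigma(curve), grid)$y
  dens <- dnorm(c14Age, mu, sqrt(sigma^2 + s^2))
  mass <- dens / sum(dens)
  grid[which(cumsum(mass) >= 0.5)[1]]
}

# Smallest-cell-count HPD set: for each k the best attainable mass is the sum
# of the k largest cells, so the minimal set is the top-k cells at the first
# k reaching the level. Returns the sorted cell indices.
hpdOracleCells <- function(mass, level) {
  o <- order(mass, decreasing = TRUE)
  k <- which(cumsum(mass[o]) >= level)[1]
  sort(o[seq_len(k)])
}

# 2-parameter grid integration of the uniform-phase posterior (end median).
gridPhaseEndMedian <- function(obs, sds, lo, hi, step, p = 0) {
  st <- seq(lo, hi, by = step)
  en <- st
  n <- length(obs)
  logpost <- matrix(-Inf, length(st), length(en))
  for (i in seq_along(st)) for (j in seq_along(en)) {
    if (st[i] <= en[j]) next
    ll <- sum(log(pmax(pnorm(st[i], obs, sds) - pnorm(en[j], obs, sds),
      1e-300))) - (n + p) * log(st[i] - en[j])
    logpost[i, j] <- ll
  }
  w <- exp(logpost - max(logpost))
  endMarg <- colSums(w) / sum(w)
  en[which(cumsum(endMarg) >= 0.5)[1]]
}

# Plain two-way weighted averaging with inverse deshrinking (regression of
# observed climate on the WA estimates, weighted by transformed sample
# totals): the known equivalent of WA-PLS component 1.
waOracleFitted <- function(m, x, sqrtTransform = TRUE) {
  p <- m / rowSums(m)
  if (sqrtTransform) p <- sqrt(p)
  u <- colSums(p * x) / colSums(p)
  t0 <- as.numeric(p %*% u) / rowSums(p)
  unname(fitted(lm(x ~ t0, weights = rowSums(p))))
}

# Exhaustive rarefaction: enumerate every subset of baseN grains and count
# distinct taxa (feasible for tiny totals).
rarefactionOracle <- function(counts, baseN) {
  grains <- rep(seq_along(counts), counts)
  subs <- utils::combn(length(grains), baseN)
  mean(apply(subs, 2, function(ix) length(unique(grains[ix]))))
}

# batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# chain of draws
batchMeansSE <- function(draws, nBatch = 50) {
  b <- floor(length(draws) / nBatch)
  mns <- vapply(seq_len(nBatch), function(i)
    mean(draws[((i - 1) * b + 1):(i * b)]), numeric(1))
  sd(mns) / sqrt(nBatch)
}

# shared toy biomization matrices: 3 taxa, 2 PFTs, 2 biomes
toyPft <- function() {
  pftMatrix(matrix(c(
    1, 0,   # Pinus -> trees
    1, 0,   # Quercus -> trees
    0, 1),  # Artemisia -> steppe herbs
    nrow = 3, byrow = TRUE,
    dimnames = list(c("Pinus", "Quercus", "Artemisia"),
      c("trees", "herbs"))),
    arboreal = c(TRUE, TRUE, FALSE))
}

toyBiomes <- function() {
  biomeMatrix(matrix(c(
    1, 0,   # temperate forest: trees
    1, 1),  # wooded steppe: trees + herbs
    nrow = 2, byrow = TRUE,
    dimnames = list(c("temperate forest", "wooded steppe"),
      c("trees", "herbs"))))
}
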