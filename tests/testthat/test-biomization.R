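test_that("a single-PFT single-biome taxon scores sqrt of its percentage", {
  pft <- pftMatrix(matrix(1, 1, 1, dimnames = list("Pinus", "boreal trees")),
    arboreal = TRUE)
  bm <- biomeMatrix(matrix(1, 1, 1,
    dimnames = list("taiga", "boreal trees")))
  sc <- scoreAffinities(c(Pinus = 100), pft, bm)
  expect_equal(unname(sc["taiga"]), 10)  # sqrt(100)
})

test_that("taxa at or below the 0.5% threshold contribute nothing", {
  pft <- toyPft(); bm <- toyBiomes()
  sc <- scoreAffinities(c(Pinus = 99.6, Artemisia = 0.4), pft, bm)
  expect_equal(unname(sc["wooded steppe"]), sqrt(99.6))  # herb PFT empty
  sc2 <- scoreAffinities(c(Pinus = 99.4, Artemisia = 0.6), pft, bm)
  expect_equal(unname(sc2["wooded steppe"]), sqrt(99.4) + sqrt(0.6))
})

test_that("a 3-taxon 2-PFT 2-biome spectrum matches the hand calculation", {
  pft <- toyPft(); bm <- toyBiomes()
  p <- c(Pinus = 40, Quercus = 35, Artemisia = 25)
  sc <- scoreAffinities(p, pft, bm)
  treeScore <- sqrt(40) + sqrt(35)
  herbScore <- sqrt(25)
  expect_equal(unname(sc["temperate forest"]), treeScore)
  expect_equal(unname(sc["wooded steppe"]), treeScore + herbScore)
  expect_equal(unname(attr(sc, "pftScores")), c(treeScore, herbScore))
  expect_equal(attr(sc, "arborealPercent"), 75)
})

test_that("threshold 0 reduces to unthresholded square-root sums", {
  pft <- toyPft(); bm <- toyBiomes()
  p <- c(Pinus = 50.2, Quercus = 0.3, Artemisia = 49.5)
  sc0 <- scoreAffinities(p, pft, bm, threshold = 0)
  oracle <- c(sqrt(50.2) + sqrt(0.3),
    sqrt(50.2) + sqrt(0.3) + sqrt(49.5))
  expect_equal(as.numeric(sc0), oracle)
})

test_that("assignment takes the maximum with deterministic tie-breaks", {
  bm <- toyBiomes()
  a <- assignBiome(c("temperate forest" = 5, "wooded steppe" = 3), bm,
    arborealPercent = 90)
  expect_equal(as.character(a), "temperate forest")
  # exact tie: the biome with fewer defining PFTs wins
  t2 <- assignBiome(c("temperate forest" = 4, "wooded steppe" = 4), bm,
    arborealPercent = 90)
  expect_equal(as.character(t2), "temperate forest")  # 1 PFT vs 2 PFTs
  # all-zero scores are unassigned
  expect_equal(as.character(assignBiome(
    c("temperate forest" = 0, "wooded steppe" = 0), bm, 50)), "unassigned")
})

test_that("the arboreal override replaces temperate forest below the cutoff", {
  bm <- toyBiomes()
  w <- assignBiome(c("temperate forest" = 5, "wooded steppe" = 3), bm,
    arborealPercent = 65)
  expect_equal(as.character(w), "wooded steppe")
  expect_true(attr(w, "override"))
  # the override applies to temperate forest only
  v <- assignBiome(c("temperate forest" = 2, "wooded steppe" = 6), bm,
    arborealPercent = 65)
  expect_equal(as.character(v), "wooded steppe")
  expect_false(attr(v, "override"))
})

test_that("raising a taxon's share never lowers the scores it feeds", {
  pft <- toyPft(); bm <- toyBiomes()
  base <- c(Pinus = 30, Quercus = 30, Artemisia = 40)
  up <- c(Pinus = 45, Quercus = 30, Artemisia = 40)
  s0 <- scoreAffinities(base, pft, bm)
  s1 <- scoreAffinities(up, pft, bm)
  expect_gte(s1["temperate forest"], s0["temperate forest"])
  expect_gte(s1["wooded steppe"], s0["wooded steppe"])
})

test_that("unknown taxa are ignored but reported", {
  pft <- toyPft(); bm <- toyBiomes()
  sc <- scoreAffinities(c(Pinus = 60, Mystery = 40), pft, bm)
  expect_equal(attr(sc, "unassigned"), "Mystery")
  expect_equal(unname(sc["temperate forest"]), sqrt(60))
})

test_that("a downcore run switches biome exactly at the score crossover", {
  pft <- toyPft(); bm <- toyBiomes()
  # gradual transition from herb-rich to tree-rich spectra
  herb <- seq(90, 10, by = -10)
  m <- cbind(Pinus = 100 - herb, Quercus = 0, Artemisia = herb)
  rownames(m) <- paste0("d", seq_along(herb))
  pc <- pollenCounts(m, percent = TRUE)
  out <- biomize(pc, pft, bm)
  # hand-computed crossover: forest wins when sqrt(AP) > sqrt(AP)+sqrt(herb)
  # is impossible, so wooded steppe always has max score; forest never wins,
  # but the override keeps steppe below 70% AP anyway
  expect_true(all(out$biome == "wooded steppe"))
  # give forest its own weight: drop the tree PFT from wooded steppe
  bm2 <- biomeMatrix(matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
    dimnames = list(c("temperate forest", "wooded steppe"),
      c("trees", "herbs"))))
  out2 <- biomize(pc, pft, bm2, apCutoff = 0)  # disable the override
  # at the exact 50/50 tie both biomes have one PFT; input order keeps forest
  crossover <- which(sqrt(100 - herb) >= sqrt(herb))[1]
  expect_equal(out2$biome,
    c(rep("wooded steppe", crossover - 1),
      rep("temperate forest", length(herb) - crossover + 1)))
  # one assignment per sample
  expect_equal(nrow(out2), nrow(m))
})
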