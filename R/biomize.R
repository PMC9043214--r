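# Pollen biomization: plant-functional-type affinity scores and biome
# assignment with the arboreal-pollen override.

#' Biome affinity scores for one pollen spectrum
#'
#' Taxa whose percentage exceeds \code{threshold} contribute the square root
#' of their percentage to every PFT they belong to; a biome's affinity score
#' is the sum of its member PFTs' scores (a taxon feeding several PFTs of the
#' same biome is counted once per PFT). Taxa at or below the threshold
#' contribute nothing; taxa absent from the PFT matrix are ignored and
#' reported via the \code{"unassigned"} attribute.
#'
#' @param percentages named numeric vector, pollen percentages of one sample
#'   (values on the 0-100 scale).
#' @param pft a \linkS4class{PftMatrix}.
#' @param biomes a \linkS4class{BiomeMatrix} (same PFT columns).
#' @param threshold inclusion threshold in percent (default 0.5).
#' @return named numeric vector of biome affinity scores, with attributes
#'   \code{"pftScores"}, \code{"arborealPercent"} and \code{"unassigned"}.
#' @export
scoreAffinities <- function(percentages, pft, biomes, threshold = 0.5) {
  stopifnot(is(pft, "PftMatrix"), is(biomes, "BiomeMatrix"), threshold >= 0)
  if (is.null(names(percentages)))
    stop("percentages must be named by taxon", call. = FALSE)
  if (sum(percentages) <= 0)
    stop("percentages sum must be positive", call. = FALSE)
  common <- intersect(colnames(pft@membership), colnames(biomes@membership))
  if (length(common) == 0L)
    stop("PFT and biome matrices share no PFTs", call. = FALSE)
  taxa <- rownames(pft@membership)
  unassigned <- setdiff(names(percentages)[percentages > 0], taxa)
  p <- percentages[names(percentages) %in% taxa]
  contrib <- ifelse(p > threshold, sqrt(p), 0)
  M <- pft@membership[names(p), common, drop = FALSE]
  pftScores <- as.numeric(crossprod(M, contrib))
  names(pftScores) <- common
  B <- biomes@membership[, common, drop = FALSE]
  scores <- as.numeric(B %*% pftScores)
  names(scores) <- rownames(B)
  arb <- pft@arboreal[match(names(p), taxa)]
  apSum <- sum(p[arb])
  structure(scores, pftScores = pftScores,
    arborealPercent = if (sum(p) > 0) 100 * apSum / sum(p) else NA_real_,
    unassigned = unassigned)
}

#' Assign a biome from affinity scores
#'
#' The sample is assigned to the biome with the maximal affinity score. Ties
#' go to the biome defined by the fewest PFTs (a more specific biome); a
#' remaining tie keeps the first biome in matrix order. When the winner is
#' the temperate-forest biome and the arboreal pollen sum is below
#' \code{apCutoff} percent, the assignment is overridden to wooded steppe.
#'
#' @param scores named biome affinity scores (from [scoreAffinities()]).
#' @param biomes the \linkS4class{BiomeMatrix} used (for the tie-break).
#' @param arborealPercent arboreal pollen sum of the sample in percent;
#'   defaults to the attribute carried by \code{scores}.
#' @param apCutoff override cutoff in percent (default 70).
#' @param forestBiome,steppeBiome labels involved in the override.
#' @return the biome label, with attribute \code{"override"} (logical).
#' @export
assignBiome <- function(scores, biomes, arborealPercent = NULL,
    apCutoff = 70, forestBiome = "temperate forest",
    steppeBiome = "wooded steppe") {
  stopifnot(is(biomes, "BiomeMatrix"))
  if (is.null(arborealPercent))
    arborealPercent <- attr(scores, "arborealPercent")
  if (all(scores <= 0)) return(structure("unassigned", override = FALSE))
  mx <- max(scores)
  cand <- names(scores)[scores >= mx - 1e-12]
  if (length(cand) > 1L) {
    npft <- rowSums(biomes@membership[cand, , drop = FALSE])
    cand <- cand[npft == min(npft)]  # fewest defining PFTs wins
  }
  winner <- cand[1]                  # remaining tie: input order
  override <- FALSE
  if (identical(winner, forestBiome) && is.finite(arborealPercent) &&
      arborealPercent < apCutoff) {
    winner <- steppeBiome
    override <- TRUE
  }
  structure(winner, override = override)
}

#' Biomize a downcore pollen record
#'
#' Converts each sample to percentages (when given counts), scores biome
#' affinities and assigns a biome per sample, applying the arboreal-pollen
#' override.
#'
#' @param x a \linkS4class{PollenCounts}.
#' @param pft a \linkS4class{PftMatrix}.
#' @param biomes a \linkS4class{BiomeMatrix}.
#' @param threshold taxon inclusion threshold in percent (default 0.5).
#' @param apCutoff arboreal override cutoff in percent (default 70).
#' @param ... passed to [assignBiome()].
#' @return a data.frame: sample, biome, override, arboreal percent, one
#'   column per biome affinity score.
#' @export
biomize <- function(x, pft, biomes, threshold = 0.5, apCutoff = 70, ...) {
  stopifnot(is(x, "PollenCounts"))
  m <- countMatrix(x)
  if (!isPercent(x)) {
    rs <- rowSums(m)
    if (any(rs <= 0)) stop("sample with zero total count", call. = FALSE)
    m <- 100 * m / rs
  }
  scoreM <- NULL
  meta <- data.frame(sample = rownames(m), biome = NA_character_,
    override = NA, arborealPercent = NA_real_)
  for (i in seq_len(nrow(m))) {
    sc <- scoreAffinities(m[i, ], pft, biomes, threshold)
    asg <- assignBiome(sc, biomes, apCutoff = apCutoff, ...)
    if (is.null(scoreM))
      scoreM <- matrix(NA_real_, nrow(m), length(sc),
        dimnames = list(NULL, names(sc)))
    scoreM[i, ] <- as.numeric(sc)
    meta$biome[i] <- as.character(asg)
    meta$override[i] <- attr(asg, "override")
    meta$arborealPercent[i] <- attr(sc, "arborealPercent")
  }
  cbind(meta, as.data.frame(scoreM))
}
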