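# Palynological richness (Hurlbert rarefaction) and assemblage evenness.

#' Rarefied palynological richness E(T)
#'
#' Expected number of taxa in a random draw of \code{baseN} grains without
#' replacement (Hurlbert rarefaction):
#' \deqn{E(T) = \sum_j \left[ 1 - \binom{N - N_j}{n} / \binom{N}{n} \right]}
#' Computed through \code{vegan::rarefy}.
#'
#' @param counts named (or unnamed) non-negative integer counts of one
#'   sample, or a \linkS4class{PollenCounts} (one value per sample; percent
#'   matrices are rejected - rarefaction needs raw counts).
#' @param baseN rarefaction base count; for a \linkS4class{PollenCounts}
#'   the default \code{"auto"} uses the minimum sample total.
#' @return E(T) (scalar or per-sample vector).
#' @examples
#' rarefiedRichness(c(5, 3, 2), baseN = 5)
#' @export
rarefiedRichness <- function(counts, baseN = "auto") {
  if (is(counts, "PollenCounts")) {
    if (isPercent(counts))
      stop("rarefaction needs raw counts, not percentages", call. = FALSE)
    m <- countMatrix(counts)
    if (identical(baseN, "auto")) baseN <- min(rowSums(m))
    return(apply(m, 1, rarefiedRichness, baseN = baseN))
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("empty assemblage", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("rarefaction needs integer counts", call. = FALSE)
  N <- sum(counts)
  if (!identical(baseN, "auto") && baseN > N)
    stop("baseN exceeds the sample total", call. = FALSE)
  if (identical(baseN, "auto")) baseN <- N
  suppressWarnings(
    as.numeric(vegan::rarefy(matrix(round(counts), nrow = 1), baseN)))
}

#' Assemblage evenness
#'
#' \code{index = "pielou"}: Shannon H' divided by log(S) (computed on
#' proportions; undefined for a single taxon, returned as NA with flag).
#' \code{index = "hill_ratio"}: Hill N2/N1 =
#' exp(H') reciprocal-Simpson ratio, defined for any assemblage.
#'
#' @param counts non-negative counts (or percentages) of one sample, or a
#'   \linkS4class{PollenCounts}.
#' @param index \code{"pielou"} or \code{"hill_ratio"}.
#' @return evenness in (0, 1] (scalar or per-sample vector); single-taxon
#'   Pielou is NA with attribute \code{"flag" = "single-taxon"}.
#' @export
evenness <- function(counts, index = c("pielou", "hill_ratio")) {
  index <- match.arg(index)
  if (is(counts, "PollenCounts")) {
    m <- countMatrix(counts)
    return(apply(m, 1, function(r) {
      v <- evenness(r, index)
      as.numeric(v)
    }))
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("empty assemblage", call. = FALSE)
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  S <- length(p)
  if (index == "pielou") {
    if (S == 1L) {
      out <- NA_real_
      attr(out, "flag") <- "single-taxon"
      return(out)
    }
    return(H / log(S))
  }
  N1 <- exp(H)
  N2 <- 1 / sum(p^2)
  N2 / N1
}

#' Downcore diversity summary
#'
#' @param x a \linkS4class{PollenCounts} of raw counts.
#' @param baseN rarefaction base (default minimum sample total).
#' @param index evenness index (see [evenness()]).
#' @return a data.frame: sample, total, richness, ET, evenness.
#' @export
diversitySummary <- function(x, baseN = "auto",
    index = c("pielou", "hill_ratio")) {
  stopifnot(is(x, "PollenCounts"))
  index <- match.arg(index)
  m <- countMatrix(x)
  data.frame(
    sample = rownames(m),
    total = rowSums(m),
    richness = rowSums(m > 0),
    ET = rarefiedRichness(x, baseN),
    evenness = evenness(x, index),
    row.names = NULL)
}
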