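# Modern analogue technique: inverse-distance-weighted averaging over the
# closest modern spectra under the chord distance.

#' Chord distance between composition vectors
#'
#' Percentages (or counts) are converted to proportions and square-rooted;
#' the chord distance is the Euclidean distance between the transformed
#' vectors, \code{"squared-chord"} its square. A metric on the simplex.
#'
#' @param a,b non-negative composition vectors of equal length.
#' @param metric \code{"chord"} or \code{"squared-chord"}.
#' @return the distance (scalar).
#' @export
chordDistance <- function(a, b, metric = c("chord", "squared-chord")) {
  metric <- match.arg(metric)
  sa <- sum(a); sb <- sum(b)
  if (sa <= 0 || sb <= 0) stop("zero-total composition", call. = FALSE)
  d2 <- sum((sqrt(a / sa) - sqrt(b / sb))^2)
  if (metric == "chord") sqrt(d2) else d2
}

# rows of ymat are sqrt-proportion spectra; distance of each to vector y0
chordDistToAll <- function(y0, ymat, metric) {
  d2 <- rowSums(sweep(ymat, 2, y0)^2)
  d2[d2 < 0] <- 0
  if (metric == "chord") sqrt(d2) else d2
}

#' Reconstruct climate by the modern analogue technique
#'
#' For each fossil spectrum, chord distances to every training spectrum are
#' computed on the shared taxon set; the \code{k} closest spectra are
#' selected, analogues with distance above \code{threshold} are discarded as
#' bad analogues, and the estimate is the inverse-distance-weighted mean of
#' the retained analogues' climate values. A zero-distance analogue makes the
#' estimate that analogue's climate exactly. When every selected analogue
#' exceeds the threshold the sample gets a missing estimate and the
#' no-analogue flag.
#'
#' @param counts modern assemblages (\linkS4class{PollenCounts} or samples x
#'   taxa matrix).
#' @param climate numeric climate value per modern sample.
#' @param fossil fossil assemblages (\linkS4class{PollenCounts} or matrix).
#' @param k number of analogues (default 6).
#' @param threshold bad-analogue distance cut (default Inf; see
#'   [matThreshold()]).
#' @param metric distance variant (see [chordDistance()]).
#' @return a data.frame: sample, estimate, minDist, nAnalogues, flag ("" or
#'   "no-analogue").
#' @examples
#' ts <- genTrainingSet(nTaxa = 15, nSamples = 40, seed = 2)
#' matReconstruct(ts$counts, ts$climate, countMatrix(ts$counts)[1:3, ])
#' @export
matReconstruct <- function(counts, climate, fossil, k = 6, threshold = Inf,
    metric = c("chord", "squared-chord")) {
  metric <- match.arg(metric)
  m <- asCounts(counts)
  x <- as.numeric(climate)
  stopifnot(nrow(m) == length(x))
  k <- as.integer(k)
  if (k > nrow(m)) stop("k exceeds the training size", call. = FALSE)
  fm <- asCounts(fossil)
  if (is.null(rownames(fm)))
    rownames(fm) <- paste0("sample", seq_len(nrow(fm)))
  taxa <- colnames(m)
  ytr <- prepSpectra(m, sqrtTransform = TRUE)
  yfo <- prepSpectra(fm, taxa = taxa, sqrtTransform = TRUE)
  rows <- lapply(seq_len(nrow(yfo)), function(i) {
    if (sum(yfo[i, ]) <= 0)
      return(data.frame(sample = rownames(fm)[i], estimate = NA_real_,
        minDist = NA_real_, nAnalogues = 0L, flag = "no-analogue"))
    d <- chordDistToAll(yfo[i, ], ytr, metric)
    sel <- order(d)[seq_len(k)]
    keep <- sel[d[sel] <= threshold]
    if (length(keep) == 0L)
      return(data.frame(sample = rownames(fm)[i], estimate = NA_real_,
        minDist = min(d), nAnalogues = 0L, flag = "no-analogue"))
    dk <- d[keep]
    est <- if (any(dk == 0)) mean(x[keep][dk == 0]) else
      sum(x[keep] / dk) / sum(1 / dk)
    data.frame(sample = rownames(fm)[i], estimate = est, minDist = min(d),
      nAnalogues = length(keep), flag = "")
  })
  do.call(rbind, rows)
}

#' Monte-Carlo bad-analogue threshold
#'
#' Samples random pairs of training spectra, computes their chord distances,
#' and returns the requested quantile of the between-pair distance
#' distribution. The quantile is an explicit parameter (no field-wide default
#' is assumed).
#'
#' @inheritParams matReconstruct
#' @param nPairs number of random pairs (>= 100 recommended; default 1000).
#' @param probs quantile of the pair-distance distribution (default 0.05).
#' @param seed integer RNG seed.
#' @return the distance threshold.
#' @export
matThreshold <- function(counts, nPairs = 1000, probs = 0.05, seed = 1L,
    metric = c("chord", "squared-chord")) {
  metric <- match.arg(metric)
  m <- asCounts(counts)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 training samples", call. = FALSE)
  y <- prepSpectra(m, sqrtTransform = TRUE)
  set.seed(as.integer(seed))
  i <- sample.int(n, nPairs, replace = TRUE)
  j <- vapply(i, function(a) {
    b <- sample.int(n - 1L, 1L)
    if (b >= a) b + 1L else b
  }, integer(1))
  d2 <- rowSums((y[i, , drop = FALSE] - y[j, , drop = FALSE])^2)
  d <- if (metric == "chord") sqrt(pmax(d2, 0)) else pmax(d2, 0)
  unname(quantile(d, probs))
}
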