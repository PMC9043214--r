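# Weighted-averaging partial least squares (WA-PLS) calibration of species
# percentages against a single climate variable, with the standard validation
# suite (leave-one-out, randomization component selection, bootstrap errors).

# row-normalise to proportions over the included taxa, then transform.
# keeps all-zero rows as zeros (callers flag them).
prepSpectra <- function(m, taxa = NULL, sqrtTransform = TRUE) {
  m <- as.matrix(m)
  if (!is.null(taxa)) {
    out <- matrix(0, nrow(m), length(taxa),
      dimnames = list(rownames(m), taxa))
    have <- intersect(taxa, colnames(m))
    out[, have] <- m[, have, drop = FALSE]
    m <- out
  }
  rs <- rowSums(m)
  p <- m / ifelse(rs > 0, rs, 1)
  if (sqrtTransform) p <- sqrt(p)
  p
}

asCounts <- function(counts) {
  if (is(counts, "PollenCounts")) countMatrix(counts) else as.matrix(counts)
}

#' Fit a WA-PLS transfer function
#'
#' Percentages are recomputed over the included-taxon sum, optionally
#' square-root transformed, and calibrated against the climate variable by
#' weighted-averaging partial least squares. Component 1 is two-way weighted
#' averaging with inverse deshrinking (regression of observed climate on the
#' WA estimates, weighted by sample totals); later components repeat the
#' weighted-averaging cycle on the climate residuals, orthogonalized against
#' earlier components.
#'
#' @param counts modern assemblages: a \linkS4class{PollenCounts} or a
#'   samples x taxa matrix (counts or percentages).
#' @param climate numeric climate value per sample (same order).
#' @param nComponents number of components to extract (default 5).
#' @param sqrtTransform square-root transform the proportions (default TRUE).
#' @return a \linkS4class{WaplsModel}.
#' @examples
#' ts <- genTrainingSet(nTaxa = 20, nSamples = 60, seed = 1)
#' m <- waplsFit(ts$counts, ts$climate, nComponents = 3)
#' @export
waplsFit <- function(counts, climate, nComponents = 5,
    sqrtTransform = TRUE) {
  m <- asCounts(counts)
  x <- as.numeric(climate)
  stopifnot(nrow(m) == length(x), all(is.finite(x)))
  keep <- colSums(m) > 0
  if (!all(keep)) {
    warning("dropping taxa with zero total abundance: ",
      paste(colnames(m)[!keep], collapse = ", "), call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  if (any(rowSums(m) <= 0))
    stop("training samples with zero total count", call. = FALSE)
  K <- as.integer(nComponents)
  if (K > min(ncol(m), nrow(m) - 1L))
    stop("nComponents exceeds min(taxa, samples - 1)", call. = FALSE)
  constantX <- var(x) < 1e-20
  if (constantX && K > 1L)
    stop("degenerate fit: constant climate supports only 1 component",
      call. = FALSE)
  y <- prepSpectra(m, sqrtTransform = sqrtTransform)
  rs <- rowSums(y); cs <- colSums(y); tot <- sum(y)
  R <- rs / tot
  xbar <- sum(R * x)
  r <- x - xbar
  n <- nrow(y); mtax <- ncol(y)
  Fsc <- matrix(0, n, K)          # standardized site scores per component
  Esc <- matrix(0, mtax, K)       # effective taxon vectors for Fsc
  b <- numeric(K)
  fitted <- matrix(xbar, n, K)
  beta <- matrix(0, mtax, K, dimnames = list(colnames(y), NULL))
  for (k in seq_len(K)) {
    u <- as.numeric(crossprod(y, r)) / cs
    tt <- as.numeric(y %*% u) / rs
    e <- u
    if (k > 1L) for (l in seq_len(k - 1L)) {
      cl <- sum(R * tt * Fsc[, l])
      tt <- tt - cl * Fsc[, l]
      e <- e - cl * Esc[, l]
    }
    mt <- sum(R * tt)
    st <- sqrt(sum(R * (tt - mt)^2))
    if (st < 1e-12) {
      if (k == 1L && constantX) {
        # degenerate gradient: component contributes nothing, fit is xbar
        break
      }
      stop("degenerate fit: component ", k, " has no variance",
        call. = FALSE)
    }
    Fsc[, k] <- (tt - mt) / st
    Esc[, k] <- (e - mt) / st
    b[k] <- sum(R * r * Fsc[, k])
    r <- r - b[k] * Fsc[, k]
    cum <- Esc[, seq_len(k), drop = FALSE] %*% b[seq_len(k)]
    beta[, k] <- as.numeric(cum)
    fitted[, k] <- xbar + Fsc[, seq_len(k), drop = FALSE] %*% b[seq_len(k)]
  }
  new("WaplsModel", taxa = colnames(y), nComponents = K, beta = beta,
    xMean = xbar, sqrtTransform = isTRUE(sqrtTransform), fitted = fitted,
    x = x)
}

#' Predict climate for fossil assemblages from a WA-PLS model
#'
#' Fossil taxa are matched to training taxa by name; unmatched taxa are
#' dropped (reported via attribute \code{"droppedTaxa"}). Samples sharing no
#' taxa with the training set, or with zero total count, get a missing
#' estimate and a flag.
#'
#' @param model a \linkS4class{WaplsModel}.
#' @param fossil a \linkS4class{PollenCounts} or samples x taxa matrix.
#' @param component which component to use (default: the highest fitted).
#' @return a data.frame: sample, estimate (degrees C), flag ("", or
#'   "no-overlap").
#' @export
waplsPredict <- function(model, fossil, component = model@nComponents) {
  stopifnot(is(model, "WaplsModel"))
  component <- as.integer(component)
  if (component < 1L || component > model@nComponents)
    stop("component out of fitted range", call. = FALSE)
  m <- asCounts(fossil)
  if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  dropped <- setdiff(colnames(m)[colSums(m) > 0], model@taxa)
  y <- prepSpectra(m, taxa = model@taxa,
    sqrtTransform = model@sqrtTransform)
  ysum <- rowSums(y)
  est <- ifelse(ysum > 0,
    model@xMean + as.numeric(y %*% model@beta[, component]) /
      pmax(ysum, 1e-300),
    NA_real_)
  out <- data.frame(sample = rownames(m), estimate = est,
    flag = ifelse(ysum > 0, "", "no-overlap"))
  attr(out, "droppedTaxa") <- dropped
  out
}

#' Cross-validation statistics of a transfer function
#'
#' @slot stats data.frame with one row per component: r2 (measured vs
#'   predicted), RMSEP, maximum bias (largest absolute mean residual over 10
#'   equal-width climate intervals).
#' @slot predicted matrix of leave-one-out predictions (samples x components).
#' @slot observed numeric, the climate values.
#' @export
setClass("CvStatistics",
  representation(stats = "data.frame", predicted = "matrix",
    observed = "numeric"))

setMethod("show", "CvStatistics", function(object) {
  cat("Leave-one-out cross-validation:\n")
  print(object@stats, row.names = FALSE)
})

#' Leave-one-out cross-validation of WA-PLS
#'
#' Refits the model with each training sample left out in turn and predicts
#' it; reports per-component r-squared, RMSEP and maximum bias (largest
#' absolute mean residual over 10 equal-width intervals of the climate
#' gradient).
#'
#' @inheritParams waplsFit
#' @param maxComponents highest component to evaluate.
#' @return a \linkS4class{CvStatistics}.
#' @export
looCrossvalidate <- function(counts, climate, maxComponents = 5,
    sqrtTransform = TRUE) {
  m <- asCounts(counts)
  x <- as.numeric(climate)
  n <- nrow(m)
  K <- as.integer(maxComponents)
  pred <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    fit <- waplsFit(m[-i, , drop = FALSE], x[-i], nComponents = K,
      sqrtTransform = sqrtTransform)
    for (k in seq_len(K))
      pred[i, k] <- waplsPredict(fit, m[i, , drop = FALSE], k)$estimate
  }
  stats <- do.call(rbind, lapply(seq_len(K), function(k) {
    e <- pred[, k] - x
    data.frame(component = k,
      r2 = suppressWarnings(stats::cor(x, pred[, k]))^2,
      rmsep = sqrt(mean(e^2)),
      maxBias = maxBias(e, x))
  }))
  new("CvStatistics", stats = stats, predicted = pred, observed = x)
}

# largest absolute mean residual over nbin equal-width climate intervals
maxBias <- function(resid, x, nbin = 10) {
  br <- seq(min(x), max(x), length.out = nbin + 1)
  bin <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1), nbin)
  max(abs(tapply(resid, bin, mean)))
}

#' Select the WA-PLS component by randomization t-test
#'
#' Starting from component 1, component c+1 is accepted over c only when its
#' leave-one-out squared prediction errors are significantly smaller under a
#' paired sign-flip randomization test (and RMSEP actually decreases);
#' selection stops at the first non-significant step. p-values are computed
#' as (r + 1)/(n + 1).
#'
#' @param cv a \linkS4class{CvStatistics} with at least 2 components.
#' @param nRandomizations sign-flip permutations (default 999).
#' @param alpha acceptance level (default 0.05).
#' @param seed integer RNG seed.
#' @return the selected component index, with attribute \code{"pValues"}.
#' @export
selectComponent <- function(cv, nRandomizations = 999, alpha = 0.05,
    seed = 1L) {
  stopifnot(is(cv, "CvStatistics"))
  K <- ncol(cv@predicted)
  if (K < 2L) return(1L)
  set.seed(as.integer(seed))
  pvals <- rep(NA_real_, K)
  sel <- 1L
  for (k in seq_len(K - 1L)) {
    e1 <- (cv@predicted[, k] - cv@observed)^2
    e2 <- (cv@predicted[, k + 1] - cv@observed)^2
    d <- e2 - e1
    obs <- mean(d)
    flips <- vapply(seq_len(nRandomizations), function(j)
      mean(d * sample(c(-1, 1), length(d), replace = TRUE)), numeric(1))
    p <- (sum(flips <= obs) + 1) / (nRandomizations + 1)
    pvals[k + 1] <- p
    improved <- cv@stats$rmsep[k + 1] < cv@stats$rmsep[k]
    if (improved && p < alpha) sel <- k + 1L else break
  }
  structure(sel, pValues = pvals)
}

#' Bootstrap sample-specific errors for WA-PLS reconstructions
#'
#' Training samples are resampled with replacement \code{nCycles} times; each
#' cycle refits the model and predicts the fossil samples. The per-sample
#' standard error combines the spread of the bootstrap predictions (s1) with
#' the root-mean-square out-of-bag training prediction error (s2):
#' \code{se = sqrt(s1^2 + s2^2)}.
#'
#' @inheritParams waplsFit
#' @param fossil fossil assemblages (\linkS4class{PollenCounts} or matrix).
#' @param component WA-PLS component to use.
#' @param nCycles bootstrap cycles (default 1000).
#' @param seed integer RNG seed.
#' @return a data.frame: sample, estimate (full-model prediction), s1, s2,
#'   se.
#' @export
bootstrapErrors <- function(counts, climate, fossil, component = 1,
    nCycles = 1000, seed = 1L, sqrtTransform = TRUE) {
  stopifnot(nCycles >= 2)
  m <- asCounts(counts)
  x <- as.numeric(climate)
  fm <- asCounts(fossil)
  n <- nrow(m)
  full <- waplsFit(m, x, nComponents = component,
    sqrtTransform = sqrtTransform)
  base <- waplsPredict(full, fm, component)
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, nCycles, nrow(fm))
  oob <- numeric(0)
  for (c0 in seq_len(nCycles)) {
    idx <- sample.int(n, n, replace = TRUE)
    out <- setdiff(seq_len(n), unique(idx))
    fit <- tryCatch(
      suppressWarnings(waplsFit(m[idx, , drop = FALSE], x[idx],
        nComponents = component, sqrtTransform = sqrtTransform)),
      error = function(e) NULL)
    if (is.null(fit)) next
    boot[c0, ] <- waplsPredict(fit, fm, component)$estimate
    if (length(out))
      oob <- c(oob, waplsPredict(fit, m[out, , drop = FALSE],
        component)$estimate - x[out])
  }
  s1 <- apply(boot, 2, sd, na.rm = TRUE)
  s2 <- sqrt(mean(oob^2, na.rm = TRUE))
  data.frame(sample = base$sample, estimate = base$estimate,
    s1 = s1, s2 = s2, se = sqrt(s1^2 + s2^2))
}

#' Significance of a reconstruction against random environments
#'
#' Tests whether the fossil assemblage variance explained by the real
#' reconstruction exceeds what transfer functions trained on randomized
#' (permuted) climate values achieve. The statistic is the proportion of
#' variance of the (transformed) fossil spectra explained by a redundancy
#' analysis constrained on the reconstruction; the p-value is
#' (count of random >= real + 1)/(n + 1).
#'
#' Power depends on the transfer method. Weighted-averaging predictions are
#' linear functionals of the fossil composition, so when the fossil spectra
#' lie along a single compositional gradient, even random-environment WA
#' models produce reconstructions that track that gradient and the test has
#' little power; MAT null reconstructions average randomized climate values
#' over composition-chosen analogues and do not track the gradient, giving
#' the test its power. Both methods are exposed.
#'
#' @inheritParams bootstrapErrors
#' @param nRandomizations permutations of the climate vector (default 999).
#' @param method transfer function used for the real and null
#'   reconstructions: \code{"mat"} (default) or \code{"wapls"}.
#' @param k analogues for \code{method = "mat"} (default 6).
#' @return the p-value, with attributes \code{"observed"} (explained
#'   proportion) and \code{"null"} (the randomized proportions).
#' @export
reconstructionSignificance <- function(counts, climate, fossil,
    component = 1, nRandomizations = 999, seed = 1L, sqrtTransform = TRUE,
    method = c("mat", "wapls"), k = 6) {
  method <- match.arg(method)
  m <- asCounts(counts)
  x <- as.numeric(climate)
  fm <- asCounts(fossil)
  yf <- prepSpectra(fm, taxa = colnames(m), sqrtTransform = sqrtTransform)
  ok <- rowSums(yf) > 0
  yf <- yf[ok, , drop = FALSE]
  reconstruct <- function(xv) {
    if (method == "wapls") {
      fitj <- suppressWarnings(waplsFit(m, xv, nComponents = component,
        sqrtTransform = sqrtTransform))
      waplsPredict(fitj, fm, component)$estimate[ok]
    } else {
      matReconstruct(m, xv, fm, k = k)$estimate[ok]
    }
  }
  explained <- function(recon) {
    r <- vegan::rda(yf ~ recon)
    r$CCA$tot.chi / r$tot.chi
  }
  obs <- explained(reconstruct(x))
  set.seed(as.integer(seed))
  null <- vapply(seq_len(nRandomizations), function(j)
    explained(reconstruct(sample(x))), numeric(1))
  p <- (sum(null >= obs) + 1) / (nRandomizations + 1)
  structure(p, observed = obs, null = null)
}
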