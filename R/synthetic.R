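# Synthetic-data generators with known ground truth. Every generator is a
# pure function of (parameters, seed); each derives its own RNG stream from
# (seed, generator name) so adding a generator never perturbs existing
# fixtures.

streamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Generate a synthetic calibration curve
#'
#' A monotone baseline (radiocarbon age equal to calendar age on average)
#' plus smooth seeded sinusoidal wiggles; optionally a flat plateau segment
#' in the middle of the span (for multimodality tests). Amplitudes large
#' enough to break the curve's monotonicity are an error.
#'
#' @param span curve length in calendar years (>= 1000), from 0 cal BP.
#' @param wiggleAmplitude wiggle amplitude in 14C years (0 = identity curve).
#' @param seed integer master seed.
#' @param plateau insert a near-flat plateau with a small non-monotone
#'   ripple over the middle 15\% of the span; the ripple makes determinations
#'   on the plateau calibrate to multimodal densities, as on real curves.
#' @param step calendar grid step (yr, default 5).
#' @param curveSigma one-sigma curve uncertainty per grid point (default 10).
#' @return a \linkS4class{CalCurve}.
#' @examples
#' genCalCurve(5000, wiggleAmplitude = 30, seed = 1)
#' @export
genCalCurve <- function(span = 10000, wiggleAmplitude = 30, seed = 1L,
    plateau = FALSE, step = 5, curveSigma = 10) {
  stopifnot(span >= 1000)
  set.seed(streamSeed(seed, "calcurve"))
  cal <- seq(0, span, by = step)
  if (wiggleAmplitude > 0) {
    ph <- runif(3, 0, 2 * pi)
    per <- span / c(3, 7, 13)
    w <- wiggleAmplitude * (0.6 * sin(2 * pi * cal / per[1] + ph[1]) +
      0.3 * sin(2 * pi * cal / per[2] + ph[2]) +
      0.1 * sin(2 * pi * cal / per[3] + ph[3]))
  } else w <- 0
  c14 <- cal + w
  if (any(diff(c14) <= 0) && !plateau)
    stop("wiggle amplitude breaks curve monotonicity", call. = FALSE)
  if (plateau) {
    i0 <- which(cal >= 0.425 * span)[1]
    i1 <- which(cal >= 0.575 * span)[1]
    # flat stretch with a small ripple: the 14C age re-crosses the same
    # values at distinct calendar ages, the source of multimodality
    frac <- seq(0, 1, length.out = i1 - i0 + 1)
    ripple <- max(wiggleAmplitude, 3 * curveSigma)
    c14[i0:i1] <- c14[i0] + ripple * sin(6 * pi * frac)
    c14[i1:length(c14)] <- pmax(c14[i1:length(c14)], c14[i1])
    bad <- diff(c14) <= 0
    bad[(i0):(i1 - 1)] <- FALSE  # reversals allowed inside the plateau
    if (any(bad))
      stop("wiggle amplitude breaks curve monotonicity", call. = FALSE)
  }
  calCurve(cal, c14, rep(curveSigma, length(cal)))
}

#' Generate a sighting series with known extinction time
#'
#' True ages are uniform on [trueExtinction, trueExtinction + window]
#' (uniform recovery over the existence window, matching the phase model's
#' deposition assumption); observed ages add Gaussian dating error. Noise can
#' carry observed ages below the true extinction time; the truth is recorded.
#'
#' @param trueExtinction true terminal age (cal BP).
#' @param window width of the recovery window (yr).
#' @param n number of dated records (>= 2).
#' @param datingSd Gaussian dating error (yr; 0 = exact ages).
#' @param seed integer master seed.
#' @param taxon label for the series.
#' @return a list: \code{series} (\linkS4class{SightingSeries}) and
#'   \code{truth} (trueExtinction, window, n, datingSd, seed).
#' @examples
#' genSightings(12000, 3000, n = 15, datingSd = 100, seed = 7)$truth
#' @export
genSightings <- function(trueExtinction, window, n, datingSd = 50,
    seed = 1L, taxon = "synthetic taxon") {
  stopifnot(n >= 2, window > 0, datingSd >= 0)
  set.seed(streamSeed(seed, "sightings"))
  true <- runif(n, trueExtinction, trueExtinction + window)
  obs <- true + rnorm(n, 0, datingSd)
  list(
    series = sightingSeries(obs, rep(datingSd, n), taxon),
    truth = list(trueExtinction = trueExtinction, window = window, n = n,
      datingSd = datingSd, trueAges = true, seed = seed))
}

#' Generate a modern training set with Gaussian species responses
#'
#' Sample climates are uniform on \code{optimaRange}; each taxon's expected
#' abundance follows a Gaussian response curve around its (uniformly placed)
#' optimum with common \code{tolerance}; counts are multinomial draws of
#' \code{grainsPerSample} grains. Defaults are the package's standard
#' benchmark: 40 taxa with optima spread over 5-25 degrees C, tolerance 2,
#' 150 samples of 300 grains.
#'
#' @param nTaxa number of taxa (>= 2).
#' @param nSamples number of modern samples.
#' @param optimaRange range of climates and optima (degrees C).
#' @param tolerance Gaussian response breadth (degrees C); Inf gives
#'   climate-independent composition.
#' @param grainsPerSample multinomial total per sample.
#' @param seed integer master seed.
#' @return a list: \code{counts} (\linkS4class{PollenCounts}),
#'   \code{climate} (named numeric) and \code{truth} (optima, tolerance,
#'   climate, seed).
#' @export
genTrainingSet <- function(nTaxa = 40, nSamples = 150,
    optimaRange = c(5, 25), tolerance = 2, grainsPerSample = 300,
    seed = 1L) {
  stopifnot(nTaxa >= 2, nSamples >= 2)
  set.seed(streamSeed(seed, "training"))
  clim <- runif(nSamples, optimaRange[1], optimaRange[2])
  optima <- runif(nTaxa, optimaRange[1], optimaRange[2])
  taxa <- sprintf("taxon%02d", seq_len(nTaxa))
  m <- responseCounts(clim, optima, tolerance, grainsPerSample)
  dimnames(m) <- list(sprintf("mod%03d", seq_len(nSamples)), taxa)
  counts <- pollenCounts(m)
  list(counts = counts,
    climate = setNames(clim, rownames(m)),
    truth = list(optima = setNames(optima, taxa), tolerance = tolerance,
      optimaRange = optimaRange, grainsPerSample = grainsPerSample,
      climate = clim, seed = seed))
}

# multinomial counts from Gaussian responses (shared by training and fossil)
responseCounts <- function(clim, optima, tolerance, grains) {
  n <- length(clim); m <- length(optima)
  counts <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    lam <- if (is.infinite(tolerance)) rep(1, m) else
      exp(-(clim[i] - optima)^2 / (2 * tolerance^2))
    if (sum(lam) <= 0) lam <- rep(1, m)
    counts[i, ] <- as.integer(rmultinom(1, grains, lam / sum(lam)))
  }
  counts
}

#' Generate a downcore fossil sequence from a known temperature trajectory
#'
#' Samples are drawn from the same Gaussian response model as the training
#' set (its \code{truth} is passed in), at the trajectory's temperatures.
#' Trajectory values outside the training range trigger a warning
#' (extrapolation test mode), not an error.
#'
#' @param trajectory downcore temperatures (degrees C), oldest last or in any
#'   stratigraphic order the caller prefers.
#' @param truth the \code{truth} element returned by [genTrainingSet()].
#' @param grains multinomial total per sample (default the training value).
#' @param seed integer master seed.
#' @param ages optional ages (cal BP) attached to the samples.
#' @return a list: \code{counts} (\linkS4class{PollenCounts}) and
#'   \code{truth} (the trajectory and seed).
#' @export
genFossilSequence <- function(trajectory, truth, grains = NULL, seed = 1L,
    ages = NULL) {
  stopifnot(is.list(truth), !is.null(truth$optima))
  if (is.null(grains)) grains <- truth$grainsPerSample
  rng <- truth$optimaRange
  if (!is.null(rng) &&
      (any(trajectory < rng[1]) || any(trajectory > rng[2])))
    warning("trajectory outside the training range (extrapolation)",
      call. = FALSE)
  set.seed(streamSeed(seed, "fossil"))
  m <- responseCounts(trajectory, as.numeric(truth$optima),
    truth$tolerance, grains)
  dimnames(m) <- list(sprintf("fos%03d", seq_along(trajectory)),
    names(truth$optima))
  counts <- pollenCounts(m, age = ages)
  list(counts = counts,
    truth = list(trajectory = trajectory, grains = grains, seed = seed))
}
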