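#' @import methods
#' @importFrom stats approx cor dnorm pnorm qnorm quantile rnorm runif
#'   rmultinom median sd var setNames
#' @importFrom utils read.csv write.csv write.table packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' CalCurve: a radiocarbon calibration curve
#'
#' Maps calendar age (years cal BP, before AD 1950) to the expected
#' conventional radiocarbon age with its one-sigma uncertainty, on a grid of
#' calendar ages, in the style of the IntCal family of curves.
#'
#' @slot calAge numeric, calendar ages (cal BP), strictly increasing.
#' @slot c14Age numeric, radiocarbon ages (14C yr BP) at each grid point.
#' @slot sigma numeric, one-sigma uncertainty of \code{c14Age}, non-negative.
#'
#' @seealso [readCalCurve()], [calibrate()], [genCalCurve()]
#' @export
setClass("CalCurve",
  representation(calAge = "numeric", c14Age = "numeric", sigma = "numeric"))

setValidity("CalCurve", function(object) {
  msg <- NULL
  n <- length(object@calAge)
  if (n < 2L)
    msg <- c(msg, "calibration curve needs at least 2 grid points")
  if (length(object@c14Age) != n || length(object@sigma) != n)
    msg <- c(msg, "calAge, c14Age and sigma must have equal length")
  if (any(!is.finite(object@calAge)) || any(!is.finite(object@c14Age)) ||
      any(!is.finite(object@sigma)))
    msg <- c(msg, "curve values must be finite")
  else {
    if (any(diff(object@calAge) <= 0))
      msg <- c(msg, "calAge must be strictly increasing")
    if (any(object@sigma < 0))
      msg <- c(msg, "sigma must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' CalDensity: a normalized posterior over calendar ages
#'
#' Probability mass per calendar-age grid cell; the standard carrier both for
#' calibrated radiocarbon determinations and for phase-model boundary
#' densities.
#'
#' @slot calAge numeric, calendar-age grid (cal BP), strictly increasing.
#' @slot mass numeric, non-negative probability mass per cell, summing to 1.
#'
#' @seealso [calibrate()], [hpdInterval()], [pointEstimate()]
#' @export
setClass("CalDensity",
  representation(calAge = "numeric", mass = "numeric"))

setValidity("CalDensity", function(object) {
  msg <- NULL
  n <- length(object@calAge)
  if (n < 1L) msg <- c(msg, "empty density")
  if (length(object@mass) != n)
    msg <- c(msg, "calAge and mass must have equal length")
  else {
    if (n > 1L && any(diff(object@calAge) <= 0))
      msg <- c(msg, "calAge must be strictly increasing")
    if (any(object@mass < 0)) msg <- c(msg, "mass must be non-negative")
    if (abs(sum(object@mass) - 1) > 1e-9)
      msg <- c(msg, "mass must sum to 1 within 1e-9")
  }
  if (is.null(msg)) TRUE else msg
})

#' DatedRecords: a table of dated occurrences for one or more taxa
#'
#' Each row is one dated specimen: either an uncalibrated radiocarbon
#' determination (\code{ageType == "c14"}) or an age already on the calendar
#' scale (\code{ageType == "calibrated"}), with its one-sigma error.
#' \code{include} carries exclusion flags (burnt bone, problematic site).
#'
#' @slot taxon character, taxon label per record.
#' @slot labCode character, laboratory code per record.
#' @slot ageType character, \code{"c14"} or \code{"calibrated"}.
#' @slot age numeric, years BP.
#' @slot sigma numeric, one-sigma error in years, strictly positive.
#' @slot layer character, layer or depth label.
#' @slot include logical, whether a record enters downstream models.
#'
#' @seealso [readDatedRecords()], [sightingSeries()]
#' @export
setClass("DatedRecords",
  representation(taxon = "character", labCode = "character",
    ageType = "character", age = "numeric", sigma = "numeric",
    layer = "character", include = "logical"))

setValidity("DatedRecords", function(object) {
  msg <- NULL
  n <- length(object@age)
  lens <- c(length(object@taxon), length(object@labCode),
    length(object@ageType), length(object@sigma), length(object@layer),
    length(object@include))
  if (any(lens != n)) msg <- c(msg, "all record fields must have equal length")
  if (!all(object@ageType %in% c("c14", "calibrated")))
    msg <- c(msg, "ageType must be 'c14' or 'calibrated'")
  if (any(!is.finite(object@sigma)) || any(object@sigma <= 0))
    msg <- c(msg, "sigma must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' PollenCounts: an assemblage count (or percentage) matrix
#'
#' A \linkS4class{SummarizedExperiment} with taxa as rows and stratigraphic
#' samples as columns. \code{colData} carries \code{depth} (cm, positive
#' downward) and/or \code{age} (cal BP); \code{metadata(x)$percent} records
#' whether the assay holds percentages rather than raw counts.
#'
#' @seealso [pollenCounts()], [readCounts()], [countMatrix()]
#' @export
setClass("PollenCounts", contains = "SummarizedExperiment")

setValidity("PollenCounts", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    a <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(a))) msg <- c(msg, "counts must be finite")
    else if (any(a < 0)) msg <- c(msg, "counts must be non-negative")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "taxa names must be unique")
  if (is.null(msg)) TRUE else msg
})

#' SightingSeries: dated records of one taxon, ready for extinction models
#'
#' Calibrated-scale ages (mean and one-sigma error) for every included record
#' of a single taxon; optionally full calendar-age densities per record.
#'
#' @slot taxon character(1), taxon label.
#' @slot age numeric, calibrated ages (cal BP).
#' @slot sigma numeric, one-sigma errors (yr), strictly positive.
#' @slot densities list, optionally one \linkS4class{CalDensity} per record.
#'
#' @seealso [griwm()], [phaseFit()], [genSightings()]
#' @export
setClass("SightingSeries",
  representation(taxon = "character", age = "numeric", sigma = "numeric",
    densities = "list"))

setValidity("SightingSeries", function(object) {
  msg <- NULL
  if (length(object@taxon) != 1L) msg <- c(msg, "taxon must be length 1")
  if (length(object@age) != length(object@sigma))
    msg <- c(msg, "age and sigma must have equal length")
  if (any(!is.finite(object@age))) msg <- c(msg, "ages must be finite")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be >= 0")
  if (length(object@densities) &&
      length(object@densities) != length(object@age))
    msg <- c(msg, "densities must be empty or one per record")
  if (is.null(msg)) TRUE else msg
})

#' TerminalEstimate: a GRIWM terminal (last-appearance) date
#'
#' Result of the Gaussian-resampled inverse-weighted McInerny estimator:
#' the median terminal date over resampling iterations with its quantile
#' confidence bounds, plus the deterministic-core intermediates from the
#' mean ages (per-record weights and sighting rates).
#'
#' @slot terminal numeric(1), median terminal date (cal BP; smaller = younger).
#' @slot ciLower,ciUpper numeric(1), CI bounds in cal BP
#'   (\code{ciLower} is the younger bound).
#' @slot alpha numeric(1), significance level of the McInerny extension.
#' @slot iterations integer(1), resampling iterations used.
#' @slot seed integer(1), RNG seed used.
#' @slot weights numeric, normalized per-record weights (records 2..n).
#' @slot rates numeric, sighting rates lambda_i (records 2..n).
#' @slot draws numeric, resampled terminal dates.
#'
#' @seealso [griwm()]
#' @export
setClass("TerminalEstimate",
  representation(terminal = "numeric", ciLower = "numeric",
    ciUpper = "numeric", alpha = "numeric", iterations = "integer",
    seed = "integer", weights = "numeric", rates = "numeric",
    draws = "numeric"))

setValidity("TerminalEstimate", function(object) {
  msg <- NULL
  if (object@ciLower > object@terminal + 1e-9 ||
      object@terminal > object@ciUpper + 1e-9)
    msg <- c(msg, "terminal must lie within [ciLower, ciUpper]")
  if (is.null(msg)) TRUE else msg
})

#' BoundaryPosterior: posterior draws of a uniform-phase model
#'
#' Posterior samples of the start and end boundaries of a uniform deposition
#' phase fitted to dated records; the end boundary is the last-appearance
#' estimate. Draws are pooled over chains after burn-in and thinning.
#'
#' @slot start numeric, posterior draws of the start boundary (cal BP, older).
#' @slot end numeric, posterior draws of the end boundary (cal BP, younger).
#' @slot settings list, MCMC settings (iterations, burnin, thin, chains,
#'   spanPrior, seed).
#' @slot rhat numeric, split R-hat for (start, end).
#' @slot acceptance numeric(1), acceptance rate (1 for exact Gibbs updates).
#' @slot converged logical(1), FALSE flags split R-hat > 1.1.
#'
#' @seealso [phaseFit()]
#' @export
setClass("BoundaryPosterior",
  representation(start = "numeric", end = "numeric", settings = "list",
    rhat = "numeric", acceptance = "numeric", converged = "logical"))

setValidity("BoundaryPosterior", function(object) {
  msg <- NULL
  if (length(object@start) != length(object@end))
    msg <- c(msg, "start and end draws must have equal length")
  else if (any(object@start < object@end - 1e-9))
    msg <- c(msg, "every draw must satisfy start >= end")
  if (is.null(msg)) TRUE else msg
})

#' SpeciesOptima: vole species and their modern July temperature optima
#'
#' The constants of the vole-thermometer: each species' (or genus')
#' present-day July temperature optimum in degrees Celsius, a set of excluded
#' species (azonal, e.g. mountain taxa), and a synonym map for genus-level
#' matching.
#'
#' @slot optima named numeric, degrees C per taxon.
#' @slot excluded character, taxa never entering the reconstruction.
#' @slot synonyms named character, alternative name -> canonical name.
#'
#' @seealso [speciesOptima()], [reconstructTJuly()]
#' @export
setClass("SpeciesOptima",
  representation(optima = "numeric", excluded = "character",
    synonyms = "character"))

setValidity("SpeciesOptima", function(object) {
  msg <- NULL
  if (is.null(names(object@optima)) || anyNA(names(object@optima)))
    msg <- c(msg, "optima must be a named numeric vector")
  if (any(!is.finite(object@optima))) msg <- c(msg, "optima must be finite")
  if (is.null(msg)) TRUE else msg
})

#' TransferModel: fitted pollen-climate transfer functions
#'
#' Virtual parent of \linkS4class{WaplsModel} (weighted-averaging partial
#' least squares) and \linkS4class{MatModel} (modern analogue technique).
#'
#' @seealso [waplsFit()], [matModel()]
#' @export
setClass("TransferModel", representation("VIRTUAL"))

#' @rdname TransferModel-class
#' @slot taxa character, training taxon names (columns of the score matrix).
#' @slot nComponents integer(1), number of fitted components.
#' @slot beta matrix, taxa x components update scores; predictions for a
#'   (transformed, row-normalised) spectrum y are cumulative sums of
#'   weighted averages of \code{beta} plus the training climate mean.
#' @slot xMean numeric(1), weighted mean of the training climate.
#' @slot sqrtTransform logical(1), whether percentages were square-rooted.
#' @slot fitted matrix, training-sample fitted values per component.
#' @slot x numeric, training climate values.
#' @export
setClass("WaplsModel", contains = "TransferModel",
  representation(taxa = "character", nComponents = "integer",
    beta = "matrix", xMean = "numeric", sqrtTransform = "logical",
    fitted = "matrix", x = "numeric"))

#' @rdname TransferModel-class
#' @slot taxa character, training taxon names.
#' @slot y matrix, training proportions (samples x taxa) after square-root.
#' @slot k integer(1), number of analogues retained.
#' @slot threshold numeric(1), chord-distance cut above which an analogue is
#'   discarded.
#' @slot metric character(1), \code{"chord"} or \code{"squared-chord"}.
#' @slot x numeric, training climate values.
#' @export
setClass("MatModel", contains = "TransferModel",
  representation(taxa = "character", y = "matrix", k = "integer",
    threshold = "numeric", metric = "character", x = "numeric"))

#' PftMatrix: taxon membership of plant functional types
#'
#' A 0/1 matrix (taxa x PFTs) plus a per-taxon arboreal flag used for the
#' arboreal-pollen sum.
#'
#' @slot membership matrix, 0/1, rownames are taxa, colnames PFTs.
#' @slot arboreal logical, per-taxon tree/shrub flag.
#'
#' @seealso [readPftMatrix()], [scoreAffinities()]
#' @export
setClass("PftMatrix",
  representation(membership = "matrix", arboreal = "logical"))

setValidity("PftMatrix", function(object) {
  msg <- NULL
  m <- object@membership
  if (!all(m %in% c(0, 1))) msg <- c(msg, "membership entries must be 0/1")
  if (any(rowSums(m) < 1))
    msg <- c(msg, "every taxon must belong to at least one PFT")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "membership needs taxon rownames and PFT colnames")
  if (length(object@arboreal) != nrow(m))
    msg <- c(msg, "arboreal must have one flag per taxon")
  if (is.null(msg)) TRUE else msg
})

#' BiomeMatrix: PFT membership of biomes
#'
#' @slot membership matrix, 0/1, rownames are biomes, colnames PFTs.
#'
#' @seealso [readBiomeMatrix()], [assignBiome()]
#' @export
setClass("BiomeMatrix", representation(membership = "matrix"))

setValidity("BiomeMatrix", function(object) {
  msg <- NULL
  m <- object@membership
  if (!all(m %in% c(0, 1))) msg <- c(msg, "membership entries must be 0/1")
  if (any(rowSums(m) < 1))
    msg <- c(msg, "every biome must include at least one PFT")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "membership needs biome rownames and PFT colnames")
  if (is.null(msg)) TRUE else msg
})
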