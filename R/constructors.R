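#' Construct a calibration curve
#'
#' @param calAge calendar ages (cal BP), strictly increasing after sorting.
#' @param c14Age radiocarbon ages (14C yr BP) per grid point.
#' @param sigma one-sigma errors of \code{c14Age}.
#' @return a \linkS4class{CalCurve}. Rows are re-sorted ascending in
#'   \code{calAge}; exactly duplicated rows are collapsed, conflicting
#'   duplicates are an error.
#' @examples
#' calCurve(c(0, 100, 200), c(0, 105, 212), c(1, 2, 2))
#' @export
calCurve <- function(calAge, c14Age, sigma) {
  stopifnot(is.numeric(calAge), is.numeric(c14Age), is.numeric(sigma))
  o <- order(calAge)
  calAge <- calAge[o]; c14Age <- c14Age[o]; sigma <- sigma[o]
  if (anyDuplicated(calAge)) {
    key <- paste(calAge, c14Age, sigma)
    keep <- !duplicated(key)
    calAge <- calAge[keep]; c14Age <- c14Age[keep]; sigma <- sigma[keep]
    if (anyDuplicated(calAge))
      stop("duplicated calAge rows with conflicting values", call. = FALSE)
  }
  new("CalCurve", calAge = calAge, c14Age = c14Age, sigma = sigma)
}

#' Construct a calendar-age density
#'
#' @param calAge strictly increasing grid (cal BP).
#' @param mass non-negative masses; renormalized to sum to 1.
#' @return a \linkS4class{CalDensity}.
#' @export
calDensity <- function(calAge, mass) {
  s <- sum(mass)
  if (!is.finite(s) || s <= 0) stop("density mass must sum to > 0",
    call. = FALSE)
  new("CalDensity", calAge = as.numeric(calAge),
    mass = as.numeric(mass) / s)
}

#' Construct an assemblage count matrix
#'
#' @param counts numeric matrix, samples in rows and taxa in columns
#'   (the tabular layout of the CSV readers and writers).
#' @param depth optional depths (cm, positive downward), one per sample.
#' @param age optional ages (cal BP), one per sample.
#' @param percent logical; TRUE when the values are percentages.
#' @return a \linkS4class{PollenCounts} (stored taxa x samples).
#' @examples
#' m <- matrix(c(10, 0, 5, 20, 1, 4), nrow = 2, byrow = TRUE,
#'   dimnames = list(c("s1", "s2"), c("Pinus", "Betula", "Artemisia")))
#' pollenCounts(m, age = c(11000, 11500))
#' @export
pollenCounts <- function(counts, depth = NULL, age = NULL, percent = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sample", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    stop("counts must have taxon column names", call. = FALSE)
  cd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(depth)) cd$depth <- as.numeric(depth)
  if (!is.null(age)) cd$age <- as.numeric(age)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)), colData = cd)
  S4Vectors::metadata(se)$percent <- isTRUE(percent)
  new("PollenCounts", se)
}

#' Construct a dated-record table
#'
#' @param taxon,age,sigma,age_type record fields; \code{age_type} is
#'   \code{"c14"} or \code{"calibrated"} (recycled if length 1).
#' @param lab_code,layer optional labels.
#' @param include_flag logical inclusion flags, default all TRUE.
#' @return a \linkS4class{DatedRecords}.
#' @export
datedRecords <- function(taxon, age, sigma, age_type = "calibrated",
    lab_code = NA_character_, layer = NA_character_, include_flag = TRUE) {
  n <- length(age)
  new("DatedRecords",
    taxon = rep_len(as.character(taxon), n),
    labCode = rep_len(as.character(lab_code), n),
    ageType = rep_len(as.character(age_type), n),
    age = as.numeric(age), sigma = rep_len(as.numeric(sigma), n),
    layer = rep_len(as.character(layer), n),
    include = rep_len(as.logical(include_flag), n))
}

#' Keep only records flagged for inclusion
#'
#' Reproduces exclusion-style subsetting of dated-record tables (removal of
#' problematic sites or burnt-bone dates flagged in the input file).
#'
#' @param x a \linkS4class{DatedRecords}.
#' @return a \linkS4class{DatedRecords} with \code{include_flag == TRUE} rows.
#' @export
filterRecords <- function(x) {
  stopifnot(is(x, "DatedRecords"))
  x[x@include]
}

#' Construct a sighting series for one taxon
#'
#' @param age calibrated ages (cal BP).
#' @param sigma one-sigma errors (yr); zero allowed (treated as exact ages).
#' @param taxon taxon label.
#' @param densities optional list of \linkS4class{CalDensity}, one per record,
#'   used instead of the Gaussian when resampling.
#' @return a \linkS4class{SightingSeries}.
#' @export
sightingSeries <- function(age, sigma, taxon = "taxon", densities = list()) {
  new("SightingSeries", taxon = as.character(taxon)[1],
    age = as.numeric(age), sigma = rep_len(as.numeric(sigma), length(age)),
    densities = densities)
}

#' Sighting series from a dated-record table
#'
#' Selects one taxon's included records; \code{"c14"} records are calibrated
#' against \code{curve} and summarised as median with the mass-weighted
#' standard deviation, \code{"calibrated"} records pass through.
#'
#' @param records a \linkS4class{DatedRecords}.
#' @param taxon taxon to select.
#' @param curve a \linkS4class{CalCurve}, required when c14 records occur.
#' @param keepDensities store the full calibrated densities for resampling.
#' @return a \linkS4class{SightingSeries}.
#' @export
recordsToSeries <- function(records, taxon, curve = NULL,
    keepDensities = FALSE) {
  stopifnot(is(records, "DatedRecords"))
  r <- filterRecords(records)
  r <- r[r@taxon == taxon]
  if (length(r) == 0L) stop("no included records for taxon ", taxon,
    call. = FALSE)
  age <- r@age; sigma <- r@sigma
  dens <- list()
  isC14 <- r@ageType == "c14"
  if (any(isC14)) {
    if (is.null(curve))
      stop("c14 records present: a calibration curve is required",
        call. = FALSE)
    for (i in which(isC14)) {
      d <- calibrate(age[i], sigma[i], curve)
      age[i] <- pointEstimate(d, "median")
      mu <- sum(d@calAge * d@mass)
      sigma[i] <- sqrt(sum((d@calAge - mu)^2 * d@mass))
      if (keepDensities) dens[[i]] <- d
    }
    if (keepDensities)
      for (i in which(!isC14))
        dens[[i]] <- gaussianDensity(age[i], sigma[i])
  }
  sightingSeries(age, sigma, taxon,
    densities = if (keepDensities) dens else list())
}

#' Vole species temperature optima
#'
#' The default table of present-day July temperature optima used by the
#' vole-thermometer, with the standard exclusion of the azonal mountain
#' species Microtus nivalis, and a genus-level synonym map so that congeneric
#' species resolve to the tabulated optimum.
#'
#' @param optima named numeric vector of optima (degrees C); defaults to the
#'   standard seven-taxon table.
#' @param excluded taxa never entering the reconstruction.
#' @param synonyms named character map, alternative name -> tabulated name.
#' @return a \linkS4class{SpeciesOptima}.
#' @examples
#' speciesOptima()
#' @export
speciesOptima <- function(optima = NULL, excluded = "Microtus nivalis",
    synonyms = NULL) {
  if (is.null(optima))
    optima <- c("Clethrionomys" = 15, "Arvicola" = 17.5,
      "Microtus arvalis" = 21, "Microtus agrestis" = 19,
      "Lasiopodomys gregalis" = 10, "Microtus oeconomus" = 12.5,
      "Dicrostonyx" = 7.5)
  if (is.null(synonyms))
    synonyms <- c(
      "Clethrionomys glareolus" = "Clethrionomys",
      "Myodes glareolus" = "Clethrionomys",
      "Arvicola amphibius" = "Arvicola",
      "Arvicola terrestris" = "Arvicola",
      "Lasiopodomys (S.) gregalis" = "Lasiopodomys gregalis",
      "Microtus gregalis" = "Lasiopodomys gregalis",
      "Dicrostonyx torquatus" = "Dicrostonyx")
  new("SpeciesOptima", optima = optima, excluded = as.character(excluded),
    synonyms = synonyms)
}

#' Construct PFT and biome membership matrices
#'
#' @param membership 0/1 matrix; taxa (or biomes) in rows, PFTs in columns.
#' @param arboreal logical per-taxon flag (PFT matrix only).
#' @return a \linkS4class{PftMatrix} or \linkS4class{BiomeMatrix}.
#' @export
pftMatrix <- function(membership, arboreal) {
  new("PftMatrix", membership = as.matrix(membership),
    arboreal = as.logical(arboreal))
}

#' @rdname pftMatrix
#' @export
biomeMatrix <- function(membership) {
  new("BiomeMatrix", membership = as.matrix(membership))
}
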