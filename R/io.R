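# Tabular dialect: comma-separated, '.' decimal, UTF-8, '#' comment lines.

formatError <- function(...) stop(..., call. = FALSE)

#' Read and write calibration curves
#'
#' \code{dialect = "simple"} is a headerless 3-column CSV (cal BP, 14C age,
#' 1-sigma). \code{dialect = "intcal"} is the IntCal distribution layout:
#' '#' header lines followed by a header row and 5 columns, of which only the
#' first three (cal BP, 14C age, error) are used. Rows are re-sorted
#' ascending in calendar age.
#'
#' @param path file path.
#' @param dialect \code{"simple"} or \code{"intcal"}.
#' @return \code{readCalCurve}: a \linkS4class{CalCurve}.
#' @export
readCalCurve <- function(path, dialect = c("simple", "intcal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) formatError("file not found: ", path)
  if (dialect == "simple") {
    d <- read.csv(path, header = FALSE, comment.char = "#",
      strip.white = TRUE)
  } else {
    d <- read.csv(path, header = TRUE, comment.char = "#",
      strip.white = TRUE)
  }
  if (ncol(d) < 3L) formatError("curve file needs at least 3 columns")
  d <- d[, 1:3]
  if (!all(vapply(d, is.numeric, logical(1))))
    formatError("curve columns must be numeric")
  if (any(d[[3]] < 0)) formatError("negative sigma in curve file")
  calCurve(d[[1]], d[[2]], d[[3]])
}

#' @rdname readCalCurve
#' @param curve a \linkS4class{CalCurve} to write (simple dialect).
#' @return \code{writeCalCurve}: the path, invisibly.
#' @export
writeCalCurve <- function(curve, path) {
  stopifnot(is(curve, "CalCurve"))
  write.table(
    data.frame(curve@calAge, curve@c14Age, curve@sigma),
    path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write assemblage count tables
#'
#' The CSV layout is samples in rows: first column the sample id, optional
#' \code{depth} and/or \code{age} columns, all remaining columns taxa.
#' Percentage tables are auto-detected (every row sum within 100 +/- 1.5)
#' and flagged. Rows of all zeros are accepted on read; computations reject
#' them where they are unusable.
#'
#' @param path file path.
#' @return \code{readCounts}: a \linkS4class{PollenCounts}.
#' @export
readCounts <- function(path) {
  if (!file.exists(path)) formatError("file not found: ", path)
  d <- read.csv(path, header = TRUE, comment.char = "#", check.names = FALSE)
  if (ncol(d) < 2L) formatError("count file needs sample id + taxa columns")
  ids <- as.character(d[[1]])
  nm0 <- names(d)[-1]
  dupTaxa <- nm0[!(tolower(nm0) %in% c("depth", "age"))]
  if (anyDuplicated(dupTaxa))
    formatError("duplicated taxon column: ",
      paste(unique(dupTaxa[duplicated(dupTaxa)]), collapse = ", "))
  d <- d[, -1, drop = FALSE]
  nm <- tolower(names(d))
  depth <- if ("depth" %in% nm) as.numeric(d[[which(nm == "depth")[1]]])
  age <- if ("age" %in% nm) as.numeric(d[[which(nm == "age")[1]]])
  taxa <- d[, !(nm %in% c("depth", "age")), drop = FALSE]
  if (anyDuplicated(names(taxa)))
    formatError("duplicated taxon column: ",
      paste(unique(names(taxa)[duplicated(names(taxa))]), collapse = ", "))
  m <- as.matrix(taxa)
  if (!is.numeric(m)) formatError("taxon columns must be numeric")
  if (any(m < 0)) formatError("negative count")
  rownames(m) <- ids
  rs <- rowSums(m)
  percent <- nrow(m) > 0 && all(abs(rs - 100) <= 1.5)
  pollenCounts(m, depth = depth, age = age, percent = percent)
}

#' @rdname readCounts
#' @param x a \linkS4class{PollenCounts} to write.
#' @return \code{writeCounts}: the path, invisibly.
#' @export
writeCounts <- function(x, path) {
  stopifnot(is(x, "PollenCounts"))
  m <- countMatrix(x)
  out <- data.frame(sample = rownames(m), check.names = FALSE)
  if (!all(is.na(sampleDepths(x)))) out$depth <- sampleDepths(x)
  if (!all(is.na(sampleAges(x)))) out$age <- sampleAges(x)
  out <- cbind(out, as.data.frame(m, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write dated-record tables
#'
#' Required columns: \code{taxon}, \code{age}, \code{sigma}, \code{age_type}
#' (\code{c14} or \code{calibrated}). Optional: \code{lab_code},
#' \code{layer}, \code{include_flag} (defaults TRUE; carries burnt-bone or
#' problematic-site exclusions).
#'
#' @param path file path.
#' @return \code{readDatedRecords}: a \linkS4class{DatedRecords}.
#' @export
readDatedRecords <- function(path) {
  if (!file.exists(path)) formatError("file not found: ", path)
  d <- read.csv(path, header = TRUE, comment.char = "#")
  need <- c("taxon", "age", "sigma", "age_type")
  miss <- setdiff(need, names(d))
  if (length(miss))
    formatError("missing required column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(d$sigma)) || any(d$sigma <= 0))
    formatError("sigma must be > 0")
  if (!all(d$age_type %in% c("c14", "calibrated")))
    formatError("age_type must be 'c14' or 'calibrated'")
  datedRecords(
    taxon = d$taxon, age = d$age, sigma = d$sigma, age_type = d$age_type,
    lab_code = if ("lab_code" %in% names(d)) d$lab_code else NA_character_,
    layer = if ("layer" %in% names(d)) as.character(d$layer)
      else NA_character_,
    include_flag = if ("include_flag" %in% names(d))
      as.logical(d$include_flag) else TRUE)
}

#' @rdname readDatedRecords
#' @param x a \linkS4class{DatedRecords} to write.
#' @return \code{writeDatedRecords}: the path, invisibly.
#' @export
writeDatedRecords <- function(x, path) {
  stopifnot(is(x, "DatedRecords"))
  write.csv(recordTable(x), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read biomization matrices
#'
#' \code{readPftMatrix} expects taxa in rows (first column taxon name), one
#' 0/1 column per PFT, plus an \code{arboreal} 0/1 column. \code{readBiomeMatrix}
#' expects biomes in rows (first column biome name) and one 0/1 column per PFT.
#'
#' @param path file path.
#' @return a \linkS4class{PftMatrix} or \linkS4class{BiomeMatrix}.
#' @export
readPftMatrix <- function(path) {
  if (!file.exists(path)) formatError("file not found: ", path)
  d <- read.csv(path, header = TRUE, comment.char = "#", check.names = FALSE)
  nm <- tolower(names(d))
  if (!"arboreal" %in% nm) formatError("PFT matrix needs an arboreal column")
  rn <- as.character(d[[1]])
  arb <- as.logical(d[[which(nm == "arboreal")[1]]] > 0)
  m <- as.matrix(d[, -c(1, which(nm == "arboreal")[1]), drop = FALSE])
  rownames(m) <- rn
  pftMatrix(m, arb)
}

#' @rdname readPftMatrix
#' @export
readBiomeMatrix <- function(path) {
  if (!file.exists(path)) formatError("file not found: ", path)
  d <- read.csv(path, header = TRUE, comment.char = "#", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  biomeMatrix(m)
}

#' Read a modern training set
#'
#' Joins a modern count/percentage table with a one-value-per-sample climate
#' table (columns \code{sample} and a climate column) by sample id.
#'
#' @param countsPath path of the modern assemblage CSV (see [readCounts()]).
#' @param climatePath path of the climate CSV.
#' @param climateVar column name of the climate variable; default the first
#'   non-sample column.
#' @return a list with elements \code{counts} (\linkS4class{PollenCounts})
#'   and \code{climate} (named numeric, aligned with the samples).
#' @export
readTrainingSet <- function(countsPath, climatePath, climateVar = NULL) {
  counts <- readCounts(countsPath)
  d <- read.csv(climatePath, header = TRUE, comment.char = "#")
  if (!"sample" %in% names(d))
    formatError("climate file needs a 'sample' column")
  if (is.null(climateVar))
    climateVar <- setdiff(names(d), "sample")[1]
  if (!climateVar %in% names(d))
    formatError("climate variable not found: ", climateVar)
  ids <- colnames(counts)
  idx <- match(ids, as.character(d$sample))
  if (anyNA(idx)) formatError("climate values missing for some samples")
  clim <- setNames(as.numeric(d[[climateVar]][idx]), ids)
  if (any(!is.finite(clim))) formatError("non-finite climate value")
  list(counts = counts, climate = clim)
}

#' Write a JSON run manifest
#'
#' @param path output path.
#' @param inputs named list or character vector of input files (checksummed).
#' @param settings named list of stage settings, seeds included.
#' @param outputs character vector of output files (checksummed).
#' @param warnings character vector of accumulated warnings.
#' @return the manifest list, invisibly.
#' @export
writeManifest <- function(path, inputs = list(), settings = list(),
    outputs = character(), warnings = character()) {
  checksum <- function(f)
    if (file.exists(f)) unname(cli_md5(f)) else NA_character_
  man <- list(
    package = "paleoterm",
    version = as.character(utils::packageVersion("paleoterm")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(as.list(inputs), function(f)
      list(path = f, md5 = checksum(f))),
    settings = settings,
    outputs = lapply(as.list(outputs), function(f)
      list(path = f, md5 = checksum(f))),
    warnings = as.list(warnings))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(man)
}

cli_md5 <- function(f) tools::md5sum(f)
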