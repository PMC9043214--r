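#' Accessors for paleoterm classes
#'
#' Small accessor family: grids and masses of densities, curve columns,
#' count matrices with their sample metadata, record tables, posterior
#' draws and point summaries.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @return the slot contents in base-R form (vector, matrix or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("calAges", function(x, ...) standardGeneric("calAges"))

#' @rdname accessors
#' @export
setGeneric("c14Ages", function(x, ...) standardGeneric("c14Ages"))

#' @rdname accessors
#' @export
setGeneric("curveSigma", function(x, ...) standardGeneric("curveSigma"))

#' @rdname accessors
#' @export
setGeneric("densityMass", function(x, ...) standardGeneric("densityMass"))

#' @rdname accessors
#' @export
setGeneric("countMatrix", function(x, ...) standardGeneric("countMatrix"))

#' @rdname accessors
#' @export
setGeneric("isPercent", function(x, ...) standardGeneric("isPercent"))

#' @rdname accessors
#' @export
setGeneric("sampleAges", function(x, ...) standardGeneric("sampleAges"))

#' @rdname accessors
#' @export
setGeneric("sampleDepths", function(x, ...) standardGeneric("sampleDepths"))

#' @rdname accessors
#' @export
setGeneric("taxonNames", function(x, ...) standardGeneric("taxonNames"))

#' @rdname accessors
#' @export
setGeneric("recordTable", function(x, ...) standardGeneric("recordTable"))

#' @rdname accessors
#' @export
setGeneric("terminalAge", function(x, ...) standardGeneric("terminalAge"))

#' @rdname accessors
#' @export
setGeneric("startDraws", function(x, ...) standardGeneric("startDraws"))

#' @rdname accessors
#' @export
setGeneric("endDraws", function(x, ...) standardGeneric("endDraws"))

#' @rdname accessors
setMethod("calAges", "CalCurve", function(x, ...) x@calAge)

#' @rdname accessors
setMethod("calAges", "CalDensity", function(x, ...) x@calAge)

#' @rdname accessors
setMethod("c14Ages", "CalCurve", function(x, ...) x@c14Age)

#' @rdname accessors
setMethod("curveSigma", "CalCurve", function(x, ...) x@sigma)

#' @rdname accessors
setMethod("densityMass", "CalDensity", function(x, ...) x@mass)

#' @rdname accessors
#' @details \code{countMatrix} returns the assay as a samples x taxa base
#'   matrix (the orientation every computation in the package works in).
setMethod("countMatrix", "PollenCounts", function(x, ...)
  t(SummarizedExperiment::assay(x, "counts")))

#' @rdname accessors
setMethod("isPercent", "PollenCounts", function(x, ...)
  isTRUE(S4Vectors::metadata(x)$percent))

#' @rdname accessors
setMethod("sampleAges", "PollenCounts", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  if ("age" %in% colnames(cd)) as.numeric(cd$age) else
    rep(NA_real_, ncol(x))
})

#' @rdname accessors
setMethod("sampleDepths", "PollenCounts", function(x, ...) {
  cd <- SummarizedExperiment::colData(x)
  if ("depth" %in% colnames(cd)) as.numeric(cd$depth) else
    rep(NA_real_, ncol(x))
})

#' @rdname accessors
setMethod("taxonNames", "PollenCounts", function(x, ...) rownames(x))

#' @rdname accessors
setMethod("recordTable", "DatedRecords", function(x, ...)
  data.frame(taxon = x@taxon, lab_code = x@labCode, age_type = x@ageType,
    age = x@age, sigma = x@sigma, layer = x@layer,
    include_flag = x@include, stringsAsFactors = FALSE))

#' @rdname accessors
setMethod("terminalAge", "TerminalEstimate", function(x, ...) x@terminal)

#' @rdname accessors
setMethod("startDraws", "BoundaryPosterior", function(x, ...) x@start)

#' @rdname accessors
setMethod("endDraws", "BoundaryPosterior", function(x, ...) x@end)

#' @export
setMethod("length", "DatedRecords", function(x) length(x@age))

#' @export
setMethod("length", "SightingSeries", function(x) length(x@age))

#' Subset dated records
#'
#' @param x a \linkS4class{DatedRecords}.
#' @param i logical or integer index over records.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "DatedRecords", function(x, i, j, ..., drop = TRUE) {
  new("DatedRecords", taxon = x@taxon[i], labCode = x@labCode[i],
    ageType = x@ageType[i], age = x@age[i], sigma = x@sigma[i],
    layer = x@layer[i], include = x@include[i])
})

setMethod("show", "CalCurve", function(object) {
  cat("CalCurve:", length(object@calAge), "grid points,",
    sprintf("%.0f-%.0f cal BP\n", min(object@calAge), max(object@calAge)))
})

setMethod("show", "CalDensity", function(object) {
  med <- pointEstimate(object, "median")
  cat("CalDensity:", length(object@calAge), "cells,",
    sprintf("median %.0f cal BP\n", med))
})

setMethod("show", "DatedRecords", function(object) {
  cat("DatedRecords:", length(object@age), "records (",
    sum(object@include), "included ),",
    length(unique(object@taxon)), "taxa\n")
})

setMethod("show", "PollenCounts", function(object) {
  cat("PollenCounts:", nrow(object), "taxa x", ncol(object), "samples",
    if (isPercent(object)) "(percentages)\n" else "(counts)\n")
})

setMethod("show", "SightingSeries", function(object) {
  cat("SightingSeries for", object@taxon, ":", length(object@age),
    "records,", sprintf("%.0f-%.0f cal BP\n", min(object@age),
      max(object@age)))
})

setMethod("show", "TerminalEstimate", function(object) {
  cat(sprintf(
    "GRIWM terminal estimate: %.0f cal BP (%.0f-%.0f, alpha %.2f, %d iter)\n",
    object@terminal, object@ciLower, object@ciUpper, object@alpha,
    object@iterations))
})

setMethod("show", "BoundaryPosterior", function(object) {
  e <- quantile(object@end, c(0.5, 0.025, 0.975))
  s <- quantile(object@start, c(0.5, 0.025, 0.975))
  cat(sprintf("Phase boundaries (%d draws):\n", length(object@end)))
  cat(sprintf("  start: %.0f cal BP (95%%: %.0f-%.0f)\n", s[1], s[2], s[3]))
  cat(sprintf("  end:   %.0f cal BP (95%%: %.0f-%.0f)\n", e[1], e[2], e[3]))
  if (!object@converged) cat("  WARNING: split R-hat > 1.1\n")
})

setMethod("show", "SpeciesOptima", function(object) {
  cat("SpeciesOptima:", length(object@optima), "taxa;",
    length(object@excluded), "excluded\n")
})

setMethod("show", "WaplsModel", function(object) {
  cat("WA-PLS transfer function:", object@nComponents, "components,",
    length(object@taxa), "taxa,", length(object@x), "training samples\n")
})

setMethod("show", "MatModel", function(object) {
  cat("MAT transfer function: k =", object@k, ",", length(object@x),
    "training samples, metric", object@metric, "\n")
})

setMethod("show", "PftMatrix", function(object) {
  cat("PftMatrix:", nrow(object@membership), "taxa x",
    ncol(object@membership), "PFTs;", sum(object@arboreal),
    "arboreal taxa\n")
})

setMethod("show", "BiomeMatrix", function(object) {
  cat("BiomeMatrix:", nrow(object@membership), "biomes x",
    ncol(object@membership), "PFTs\n")
})
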