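# Vole-thermometer: July mean temperature as the percentage-weighted mean of
# species' modern temperature optima.

#' Reconstruct July mean temperature from a vole assemblage
#'
#' Percentages are computed over the counted species that carry an optimum
#' and are not excluded (azonal species such as Microtus nivalis never enter
#' numerator or denominator). Each optimum is multiplied by its species'
#' percentage, summed, and divided by 100:
#' \deqn{T_{July} = \sum_s o_s \, p_s / 100}
#' Species neither tabulated nor excluded are recorded as unassigned, dropped
#' from the denominator, and reported via a warning.
#'
#' @param counts named numeric vector of per-species counts for one sample,
#'   or a \linkS4class{PollenCounts} (one estimate per sample).
#' @param optima a \linkS4class{SpeciesOptima}; default [speciesOptima()].
#' @param minCount assemblages with fewer usable individuals are flagged
#'   low-n in the \code{"flag"} attribute (default 10).
#' @return degrees C (scalar, or vector over samples with attribute
#'   \code{"flag"}).
#' @examples
#' reconstructTJuly(c("Dicrostonyx" = 12))                    # 7.5
#' reconstructTJuly(c("Microtus arvalis" = 5, "Dicrostonyx" = 5))  # 14.25
#' @export
reconstructTJuly <- function(counts, optima = speciesOptima(),
    minCount = 10) {
  stopifnot(is(optima, "SpeciesOptima"))
  if (is(counts, "PollenCounts")) {
    m <- countMatrix(counts)
    vals <- apply(m, 1, function(row)
      tryCatch(reconstructTJuly(row, optima, minCount),
        error = function(e) NA_real_))
    flags <- apply(m, 1, function(row) {
      u <- usableVoleCounts(row, optima)
      if (sum(u) < minCount) "low-n" else ""
    })
    attr(vals, "flag") <- flags
    return(vals)
  }
  u <- usableVoleCounts(counts, optima)
  if (length(u) == 0L || sum(u) <= 0)
    stop("no usable species for the vole thermometer", call. = FALSE)
  pct <- 100 * u / sum(u)
  o <- optima@optima[names(u)]
  val <- sum(o * pct) / 100
  attr(val, "flag") <- if (sum(u) < minCount) "low-n" else ""
  val
}

# resolve synonyms, drop excluded species, warn on unassigned taxa
usableVoleCounts <- function(counts, optima) {
  nm <- names(counts)
  if (is.null(nm)) stop("counts must be named by species", call. = FALSE)
  mapped <- ifelse(nm %in% names(optima@synonyms),
    optima@synonyms[nm], nm)
  excl <- mapped %in% optima@excluded | nm %in% optima@excluded
  known <- mapped %in% names(optima@optima)
  unassigned <- nm[!known & !excl & counts > 0]
  if (length(unassigned))
    warning("unassigned taxa dropped from the denominator: ",
      paste(unassigned, collapse = ", "), call. = FALSE)
  keep <- known & !excl & counts > 0
  out <- as.numeric(counts[keep])
  names(out) <- mapped[keep]
  # merge counts mapping to the same optimum entry
  tapplyv <- tapply(out, names(out), sum)
  setNames(as.numeric(tapplyv), names(tapplyv))
}

#' Relative frequencies within a species group
#'
#' Per-sample percentages of each listed species over the group total
#' (e.g. vole percentages over all voles). Samples whose group total is zero
#' yield a row of NA, not zeros.
#'
#' @param x a \linkS4class{PollenCounts} (any assemblage count matrix).
#' @param group character, the species forming the denominator.
#' @return a samples x group percentage matrix.
#' @export
relativeFrequencies <- function(x, group) {
  stopifnot(is(x, "PollenCounts"), length(group) > 0)
  m <- countMatrix(x)
  g <- matrix(0, nrow(m), length(group),
    dimnames = list(rownames(m), group))
  have <- intersect(group, colnames(m))
  g[, have] <- m[, have, drop = FALSE]
  tot <- rowSums(g)
  out <- 100 * g / tot
  out[tot == 0, ] <- NA_real_
  out
}
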