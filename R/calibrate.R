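#' Calibrate a radiocarbon determination
#'
#' Converts a conventional radiocarbon age with its one-sigma error into a
#' normalized posterior density over calendar ages. On a regular calendar-age
#' grid, the posterior mass at age t is proportional to the Gaussian density
#' of the measured 14C age at the curve's expected 14C age, with variance
#' equal to the sum of measurement and curve variances:
#' \deqn{p(t) \propto N(y; \mu(t), \sqrt{\sigma^2 + s(t)^2})}
#' where \eqn{\mu(t)} and \eqn{s(t)} are linear interpolations of the curve.
#' Cells with mass below 1e-12 of the peak are truncated before
#' renormalization.
#'
#' @param c14Age measured radiocarbon age (14C yr BP).
#' @param sigma one-sigma measurement error (> 0).
#' @param curve a \linkS4class{CalCurve}.
#' @param gridStep calendar grid step in years (default 1).
#' @return a \linkS4class{CalDensity}.
#' @examples
#' crv <- genCalCurve(span = 8000, wiggleAmplitude = 0, seed = 1)
#' d <- calibrate(5000, 50, crv)
#' pointEstimate(d, "median")
#' hpdInterval(d, 0.95)
#' @export
calibrate <- function(c14Age, sigma, curve, gridStep = 1) {
  stopifnot(is(curve, "CalCurve"), sigma > 0, gridStep > 0)
  rng <- range(curve@c14Age)
  if (c14Age < rng[1] - 10 * sigma || c14Age > rng[2] + 10 * sigma)
    stop("determination outside the curve's 14C range (+/- 10 sigma)",
      call. = FALSE)
  grid <- seq(min(curve@calAge), max(curve@calAge), by = gridStep)
  mu <- approx(curve@calAge, curve@c14Age, grid)$y
  s <- approx(curve@calAge, curve@sigma, grid)$y
  dens <- dnorm(c14Age, mean = mu, sd = sqrt(sigma^2 + s^2))
  if (!any(dens > 0))
    stop("determination entirely outside curve support", call. = FALSE)
  idx <- which(dens >= 1e-12 * max(dens))
  keep <- seq(min(idx), max(idx))  # keep the grid regular across modes
  calDensity(grid[keep], dens[keep])
}

#' A Gaussian density on the calendar scale
#'
#' Utility used when a record is already calibrated: a discretized Normal
#' over +/- 8 sigma.
#'
#' @param mean,sd Gaussian parameters (cal BP, yr).
#' @param gridStep grid step in years.
#' @return a \linkS4class{CalDensity}.
#' @export
gaussianDensity <- function(mean, sd, gridStep = 1) {
  stopifnot(sd > 0)
  grid <- seq(mean - 8 * sd, mean + 8 * sd, by = gridStep)
  calDensity(grid, dnorm(grid, mean, sd))
}

#' Highest-posterior-density interval(s)
#'
#' The smallest set of grid cells (by cell count) whose total mass reaches
#' \code{level}, reported as maximal contiguous calendar-age intervals. With
#' multimodal densities (calibration-curve plateaus) the set splits into
#' several disjoint intervals.
#'
#' @param d a \linkS4class{CalDensity}.
#' @param level coverage fraction in (0, 1); default 0.95.
#' @return a data.frame with columns \code{lower}, \code{upper} (cal BP) and
#'   \code{mass} per interval; total attained mass in attribute
#'   \code{"totalMass"}.
#' @export
hpdInterval <- function(d, level = 0.95) {
  stopifnot(is(d, "CalDensity"), level > 0, level < 1)
  o <- order(d@mass, decreasing = TRUE)
  cum <- cumsum(d@mass[o])
  k <- which(cum >= level)[1]
  if (is.na(k)) k <- length(o)
  sel <- sort(o[seq_len(k)])
  brk <- c(0, which(diff(sel) > 1), length(sel))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1), function(i) {
    idx <- sel[(brk[i] + 1):brk[i + 1]]
    data.frame(lower = d@calAge[idx[1]], upper = d@calAge[idx[length(idx)]],
      mass = sum(d@mass[idx]))
  }))
  attr(out, "totalMass") <- sum(out$mass)
  out
}

#' Point estimates of a calendar-age density
#'
#' Median is the smallest grid age whose cumulative mass reaches 0.5; mode is
#' the argmax (ties resolved toward the older age); mean is the mass-weighted
#' average.
#'
#' @param d a \linkS4class{CalDensity}.
#' @param kind \code{"median"}, \code{"mode"} or \code{"mean"}.
#' @return years cal BP.
#' @export
pointEstimate <- function(d, kind = c("median", "mode", "mean")) {
  stopifnot(is(d, "CalDensity"))
  kind <- match.arg(kind)
  switch(kind,
    median = d@calAge[which(cumsum(d@mass) >= 0.5)[1]],
    mode = {
      mx <- max(d@mass)
      max(d@calAge[d@mass == mx])  # ties -> older age
    },
    mean = sum(d@calAge * d@mass))
}

#' Calibrate every c14 record of a table
#'
#' Convenience wrapper: calibrates each \code{age_type == "c14"} record and
#' reports the median with its 95\% HPD; calibrated records pass through with
#' Gaussian 95\% bounds.
#'
#' @param records a \linkS4class{DatedRecords}.
#' @param curve a \linkS4class{CalCurve}.
#' @param level HPD level (default 0.95).
#' @param gridStep calendar grid step (yr).
#' @return a data.frame: taxon, lab_code, median, lower, upper (outermost
#'   HPD bounds), n_intervals.
#' @export
calibrateRecords <- function(records, curve, level = 0.95, gridStep = 1) {
  stopifnot(is(records, "DatedRecords"))
  rows <- lapply(seq_len(length(records)), function(i) {
    if (records@ageType[i] == "c14") {
      d <- calibrate(records@age[i], records@sigma[i], curve, gridStep)
      h <- hpdInterval(d, level)
      data.frame(taxon = records@taxon[i], lab_code = records@labCode[i],
        median = pointEstimate(d, "median"),
        lower = min(h$lower), upper = max(h$upper),
        n_intervals = nrow(h))
    } else {
      z <- qnorm(1 - (1 - level) / 2)
      data.frame(taxon = records@taxon[i], lab_code = records@labCode[i],
        median = records@age[i],
        lower = records@age[i] - z * records@sigma[i],
        upper = records@age[i] + z * records@sigma[i],
        n_intervals = 1L)
    }
  })
  do.call(rbind, rows)
}
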