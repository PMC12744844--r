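## Melting temperature from UV absorbance melting curves by the
## second-derivative method: smooth the A260 series with a centered local
## quadratic (Savitzky-Golay) filter, differentiate numerically, and take
## the temperature where the second derivative changes sign nearest the
## extremum of the first derivative.

#' Estimate Tm from an absorbance-vs-temperature curve
#'
#' The absorbance series is smoothed by a centered local quadratic
#' (Savitzky-Golay) filter, first and second derivatives are computed by
#' central differences, and Tm is the temperature of the second-derivative
#' sign change nearest the global extremum of the first derivative,
#' refined by linear interpolation between the bracketing grid points.
#' Raw smoothed absorbance is differentiated directly; no fraction-folded
#' baseline normalisation is applied. A curve with no detectable
#' transition (for example, strictly linear absorbance) yields a
#' not-estimable sentinel.
#'
#' @param temperature numeric series, degrees Celsius, strictly monotone
#'   within the ramp; a descending (cooling) ramp is reversed internally.
#' @param absorbance A260 series, same length, >= 15 points.
#' @param smoothingWindow odd integer >= 5 and below the series length.
#'   The default (NULL) uses 21 points -- 10 degrees at the usual 0.5
#'   degree spacing, comfortably narrower than a duplex melting
#'   transition and symmetric, hence unbiased at the midpoint -- reduced
#'   to fit shorter series.
#' @return a [TmEstimate-class].
#' @examples
#' sim <- simulateMelting(tm = 60, noiseSd = 0, seed = 1)
#' estimateTm(sim$curve$temperature_C, sim$curve$a260)
#' @export
estimateTm <- function(temperature, absorbance, smoothingWindow = NULL) {
  n <- length(temperature)
  stopifnot(length(absorbance) == n)
  if (n < 15L) stop("melting curve needs at least 15 points")
  if (is.null(smoothingWindow))
    smoothingWindow <- min(21L, n - 1L - (n %% 2L))
  dT <- diff(temperature)
  if (all(dT < 0)) {         # cooling ramp supplied: reverse
    temperature <- rev(temperature)
    absorbance <- rev(absorbance)
    dT <- -rev(dT)
  }
  if (any(dT <= 0))
    stop("temperature must be strictly monotone within a ramp")
  smoothingWindow <- as.integer(smoothingWindow)
  if (smoothingWindow %% 2L == 0L || smoothingWindow < 5L ||
      smoothingWindow >= n)
    stop("smoothingWindow must be an odd integer >= 5 and below the ",
         "series length")
  sm <- signal::sgolayfilt(absorbance, p = 2, n = smoothingWindow)
  dT <- diff(temperature)
  if (diff(range(dT)) < 1e-9) {
    ## uniform grid: local-quadratic (Savitzky-Golay) derivative filters,
    ## which smooth the derivatives as they estimate them
    h <- dT[1L]
    d1 <- signal::sgolayfilt(sm, p = 2, n = smoothingWindow, m = 1) / h
    d2 <- signal::sgolayfilt(sm, p = 3, n = smoothingWindow, m = 2) / h^2
  } else {
    d1 <- .centralDiff(temperature, sm)
    d2 <- .centralDiff(temperature, d1)
  }

  ## transition guard: a (near-)linear curve has negligible curvature
  aScale <- diff(range(absorbance))
  tScale <- diff(range(temperature))
  if (aScale == 0 || max(abs(d2), na.rm = TRUE) * tScale^2 < 1e-6 * aScale)
    return(new("TmEstimate", estimable = FALSE, tm = NA_real_,
               method = "second_derivative",
               smoothingWindow = smoothingWindow))

  iExt <- which.max(abs(d1))
  sgn <- sign(d2)
  flips <- which(sgn[-n] * sgn[-1L] < 0)
  if (!length(flips))
    return(new("TmEstimate", estimable = FALSE, tm = NA_real_,
               method = "second_derivative",
               smoothingWindow = smoothingWindow))
  i <- flips[which.min(abs(flips + 0.5 - iExt))]
  tm <- temperature[i] - d2[i] * (temperature[i + 1L] - temperature[i]) /
    (d2[i + 1L] - d2[i])
  new("TmEstimate", estimable = TRUE, tm = tm,
      method = "second_derivative", smoothingWindow = smoothingWindow)
}

## central differences on a possibly non-uniform grid, one-sided at ends
.centralDiff <- function(t, y) {
  n <- length(y)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (t[2L] - t[1L])
  d[n] <- (y[n] - y[n - 1L]) / (t[n] - t[n - 1L])
  i <- 2L:(n - 1L)
  d[i] <- (y[i + 1L] - y[i - 1L]) / (t[i + 1L] - t[i - 1L])
  d
}

#' Delta Tm against an unmodified reference
#'
#' @param tmModified Tm of the modified duplex, degrees Celsius (a
#'   numeric scalar or a [TmEstimate-class]).
#' @param tmReference Tm of the unmodified reference duplex; defaults to
#'   74.5 degrees Celsius, the unmodified vimentin-targeting duplex
#'   reference.
#' @return numeric, `tmModified - tmReference` in degrees Celsius.
#' @examples
#' deltaTm(71.4, 74.5)  # -3.1
#' @export
deltaTm <- function(tmModified, tmReference = 74.5) {
  if (is(tmModified, "TmEstimate")) tmModified <- resultValue(tmModified)
  if (is(tmReference, "TmEstimate")) tmReference <- resultValue(tmReference)
  stopifnot(is.finite(tmModified), is.finite(tmReference))
  tmModified - tmReference
}

#' Split a two-way temperature program into ramps
#'
#' Instruments commonly record a heating and a cooling ramp in one trace
#' (e.g. 90 to 30 and back to 90 degrees). This splits the trace at
#' direction reversals; by default Tm analysis uses the heating ramp.
#'
#' @param temperature,absorbance the recorded series.
#' @return list of data.frames (`temperature_C`, `a260`) with a `ramp`
#'   attribute of `"heating"` or `"cooling"` each.
#' @export
splitRamps <- function(temperature, absorbance) {
  stopifnot(length(temperature) == length(absorbance))
  s <- sign(diff(temperature))
  breaks <- which(diff(s) != 0)
  bounds <- unique(c(0L, breaks + 1L, length(temperature)))
  out <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    if (length(idx) < 2L) next
    seg <- data.frame(temperature_C = temperature[idx],
                      a260 = absorbance[idx])
    attr(seg, "ramp") <- if (temperature[idx[2L]] > temperature[idx[1L]])
      "heating" else "cooling"
    out[[length(out) + 1L]] <- seg
  }
  out
}
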