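## Dual-luciferase reporter analytics: relative activity against a
## control siRNA, substantial off-target activity (SOA), and IC50 by
## log-scale bracketing interpolation.

#' Relative luciferase activity
#'
#' Per replicate, Renilla luminescence is normalised by the firefly
#' co-transfection control; the sample mean ratio is then expressed as a
#' percentage of the control (unrelated-siRNA) mean ratio. The standard
#' deviation is propagated from the sample replicates on the same scale.
#'
#' @param samples,controls data.frames with numeric columns `renilla` and
#'   `firefly`, one row per replicate.
#' @return list with components `value` (% of control), `sd` (%),
#'   `n` (sample replicates).
#' @examples
#' ctl <- data.frame(renilla = c(100, 110, 90), firefly = c(200, 210, 190))
#' smp <- data.frame(renilla = c(50, 55, 45), firefly = c(200, 200, 200))
#' relativeActivity(smp, ctl)
#' @export
relativeActivity <- function(samples, controls) {
  for (df in list(samples, controls)) {
    if (!all(c("renilla", "firefly") %in% names(df)))
      stop("reporter tables need columns 'renilla' and 'firefly'")
    if (!nrow(df)) stop("need at least one replicate")
    if (any(df$renilla <= 0) || any(df$firefly <= 0))
      stop("luminescence values must be positive")
  }
  rs <- samples$renilla / samples$firefly
  rc <- controls$renilla / controls$firefly
  value <- mean(rs) / mean(rc) * 100
  s <- if (length(rs) > 1L) stats::sd(rs) / mean(rc) * 100 else NA_real_
  list(value = value, sd = s, n = length(rs))
}

#' Substantial off-target activity (SOA)
#'
#' Rescales the modified siRNA's relative off-target reporter activity
#' against the unmodified siRNA's:
#' `SOA = (rel_modified - rel_unmodified) / (100 - rel_unmodified) * 100`.
#' SOA is 0 when the modification changes nothing and 100 when the
#' off-target reporter is fully derepressed; values outside 0-100 are
#' reported as computed, without clamping.
#'
#' @param relModified,relUnmodified relative luciferase activities (%) of
#'   the modified and unmodified siRNA on the seed-matched reporter.
#' @return an [SOAResult-class].
#' @examples
#' resultValue(soa(60, 20))  # 50
#' @export
soa <- function(relModified, relUnmodified) {
  stopifnot(is.finite(relModified), is.finite(relUnmodified))
  if (relUnmodified == 100)
    stop("SOA undefined: unmodified relative activity equals 100% ",
         "(zero denominator)")
  value <- (relModified - relUnmodified) / (100 - relUnmodified) * 100
  new("SOAResult", value = value, relModified = relModified,
      relUnmodified = relUnmodified)
}

#' IC50 by log-scale bracketing interpolation
#'
#' If 50% inhibition is hit exactly at a tested concentration, that
#' concentration is returned. Otherwise the lowest-concentration adjacent
#' pair bracketing 50% is interpolated on the log-concentration scale:
#' `IC50 = 10^(log10(A/B) * (50 - C)/(D - C) + log10(B))`, where A is the
#' bracket concentration with inhibition below 50% (inhibition D) and B
#' the one above (inhibition C). A curve that never crosses 50% yields a
#' not-estimable sentinel rather than an error.
#'
#' @param concentration numeric vector of tested concentrations (nM),
#'   >= 2 values.
#' @param inhibition numeric vector of inhibition percentages, same
#'   length.
#' @return an [IC50Result-class].
#' @examples
#' resultValue(ic50(c(0.1, 1), c(40, 60)))  # 10^-0.5 = 0.3162
#' @export
ic50 <- function(concentration, inhibition) {
  stopifnot(length(concentration) == length(inhibition),
            length(concentration) >= 2L,
            all(is.finite(concentration)), all(is.finite(inhibition)),
            all(concentration > 0))
  ord <- order(concentration)
  conc <- concentration[ord]
  inh <- inhibition[ord]
  hit <- which(inh == 50)
  if (length(hit))
    return(new("IC50Result", estimable = TRUE, ic50 = conc[hit[1L]],
               bracket = c(A = NA_real_, B = NA_real_,
                           C = NA_real_, D = NA_real_)))
  cross <- which((inh[-length(inh)] - 50) * (inh[-1L] - 50) < 0)
  if (!length(cross))
    return(new("IC50Result", estimable = FALSE, ic50 = NA_real_,
               bracket = c(A = NA_real_, B = NA_real_,
                           C = NA_real_, D = NA_real_)))
  i <- cross[1L]  # lowest-concentration crossing: conservative estimate
  lowSide <- if (inh[i] < 50) i else i + 1L
  highSide <- if (inh[i] < 50) i + 1L else i
  A <- conc[lowSide]; D <- inh[lowSide]
  B <- conc[highSide]; C <- inh[highSide]
  est <- 10^(log10(A / B) * (50 - C) / (D - C) + log10(B))
  new("IC50Result", estimable = TRUE, ic50 = est,
      bracket = c(A = A, B = B, C = C, D = D))
}

#' Welch two-sample t test
#'
#' Thin wrapper comparing modified-vs-unmodified replicate activities
#' without assuming equal variances.
#'
#' @param x,y numeric replicate vectors.
#' @return the `htest` object from [stats::t.test()].
#' @export
welchT <- function(x, y) stats::t.test(x, y, var.equal = FALSE)

#' One-way ANOVA p value
#'
#' Thin wrapper around [stats::aov()] for multi-condition activity
#' comparisons.
#'
#' @param value numeric response vector.
#' @param group grouping factor.
#' @return the ANOVA F-test p value.
#' @export
onewayAnova <- function(value, group) {
  fit <- stats::aov(value ~ factor(group))
  summary(fit)[[1L]][["Pr(>F)"]][1L]
}
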