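## Correlation machinery linking the distortion score (or delta-Tm) to
## substantial off-target activity: Pearson r with Fisher-z 95%
## confidence intervals, least-squares fits with mean-response confidence
## bands, and grouped correlation reports over position ranges.

#' Pearson correlation with Fisher confidence interval
#'
#' Sample Pearson r; two-sided p from `t = r * sqrt((n-2)/(1-r^2))` on
#' n - 2 df; 95% confidence interval by the Fisher z transform
#' (`atanh(r) +/- z_{0.975}/sqrt(n-3)`, available from n = 4). A zero
#' variance in either series yields an undefined-correlation sentinel.
#'
#' @param x,y numeric series of equal length, n >= 3, finite.
#' @return a [CorrelationReport-class].
#' @examples
#' pearsonCorrelation(1:6, c(2, 3, 5, 6, 9, 11))
#' @export
pearsonCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("series must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(new("CorrelationReport", estimable = FALSE, r = NA_real_,
               n = as.integer(n), p = NA_real_,
               ci95 = c(NA_real_, NA_real_)))
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  ci <- if (n >= 4L) {
    z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
    half <- stats::qnorm(0.975) / sqrt(n - 3)
    tanh(c(z - half, z + half))
  } else c(NA_real_, NA_real_)
  new("CorrelationReport", estimable = TRUE, r = r, n = as.integer(n),
      p = p, ci95 = ci)
}

#' Least-squares fit with mean-response confidence band
#'
#' Ordinary least-squares line plus the pointwise confidence band for the
#' mean response (the shaded band of a regression scatter plot), from the
#' t distribution with n - 2 df. This is a confidence band, not a
#' prediction band. For exactly collinear data the residual variance is
#' zero and the band collapses onto the line.
#'
#' @param x,y numeric series, n >= 3.
#' @param level confidence level, default 0.95.
#' @param gridLength number of grid points spanning the x range.
#' @return a [RegressionBand-class].
#' @export
fitWithBand <- function(x, y, level = 0.95, gridLength = 101L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0) stop("degenerate x: zero variance")
  fit <- stats::lm(y ~ x)
  grid <- seq(min(x), max(x), length.out = gridLength)
  pr <- stats::predict(fit, newdata = data.frame(x = grid),
                       interval = "confidence", level = level)
  new("RegressionBand",
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      level = level,
      band = data.frame(x = grid, fit = pr[, "fit"],
                        lower = pr[, "lwr"], upper = pr[, "upr"]))
}

.DEFAULT_GROUPINGS <- list("2-8" = 2:8, "2-5" = 2:5, "6-8" = 6:8)

#' Grouped correlations of distortion scores with SOA
#'
#' For each window combination present in the table and each position
#' grouping, correlates the distortion score against SOA over the
#' (modification, position) points in the group. The seed region splits
#' naturally into positions 2-5 (distortion-dominated) and 6-8
#' (thermodynamics-dominated); the defaults evaluate 2-8, 2-5 and 6-8.
#' Groups with fewer than 3 points yield an explicit sentinel row rather
#' than silence.
#'
#' @param table data.frame with columns `position`, `modification`,
#'   `combination`, `sirmsd_A` (or another score column named by
#'   `scoreColumn`) and `soa_pct`.
#' @param groupings named list of position vectors; default positions
#'   2-8, 2-5, 6-8. Add `perPosition = TRUE` to also report each position
#'   alone.
#' @param perPosition also report one correlation per single position.
#' @param scoreColumn name of the score column, default `"sirmsd_A"`.
#' @return data.frame with one row per (combination, grouping):
#'   `combination`, `grouping`, `n`, `r`, `p`, `ci_low`, `ci_high`,
#'   `estimable`, in deterministic order.
#' @export
groupedCorrelations <- function(table, groupings = .DEFAULT_GROUPINGS,
                                perPosition = FALSE,
                                scoreColumn = "sirmsd_A") {
  need <- c("position", "combination", scoreColumn, "soa_pct")
  if (!all(need %in% names(table)))
    stop("table is missing column(s): ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if (perPosition) {
    pp <- lapply(sort(unique(table$position)), identity)
    names(pp) <- paste0("pos", sort(unique(table$position)))
    groupings <- c(groupings, pp)
  }
  combos <- intersect(names(.WINDOW_COMBINATIONS),
                      unique(table$combination))
  if (!length(combos)) combos <- sort(unique(table$combination))
  rows <- list()
  for (comb in combos) {
    for (g in names(groupings)) {
      sub <- table[table$combination == comb &
                   table$position %in% groupings[[g]], , drop = FALSE]
      if (nrow(sub) < 3L) {
        rows[[length(rows) + 1L]] <- data.frame(
          combination = comb, grouping = g, n = nrow(sub),
          r = NA_real_, p = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, estimable = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      rep <- pearsonCorrelation(sub[[scoreColumn]], sub$soa_pct)
      rows[[length(rows) + 1L]] <- data.frame(
        combination = comb, grouping = g, n = rep@n,
        r = rep@r, p = rep@p, ci_low = rep@ci95[1L],
        ci_high = rep@ci95[2L], estimable = rep@estimable,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
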