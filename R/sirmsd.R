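## The distortion statistic: root-mean-square deviation of nucleobase
## heavy-atom positions between a chemically modified and an unmodified
## guide structure sharing one coordinate frame, per nucleotide and over
## windows of the N-1/N/N+1 nucleotides flanking the modified position N.

#' Single siRMSD value from an atom pairing
#'
#' sqrt of the mean squared per-atom distance: with per-pair distances
#' delta_i over K pairs, siRMSD = sqrt(sum(delta_i^2) / K), in Angstroms.
#'
#' @param pairing an [AtomPairing-class] with K >= 1.
#' @return numeric scalar, Angstroms.
#' @examples
#' m <- makeGuideStructure("UACGGAUCA")
#' sirmsdSingle(pairByName(translateStructure(m, c(0.3, 0, 0.4)), m))  # 0.5
#' @export
sirmsdSingle <- function(pairing) {
  stopifnot(is(pairing, "AtomPairing"))
  if (pairCount(pairing) < 1L)
    stop("empty pairing: siRMSD needs at least one atom pair")
  sqrt(mean(pairTable(pairing)$delta^2))
}

.offsetsFromWindow <- function(window) {
  if (is.numeric(window)) {
    off <- as.integer(window)
  } else {
    lab <- tolower(gsub("\\s", "", unlist(strsplit(window, "[,/]"))))
    map <- c("n-1" = -1L, "n" = 0L, "n+1" = 1L)
    off <- map[lab]
    if (anyNA(off))
      stop("unrecognised window member(s): ",
           paste(lab[is.na(off)], collapse = ", "),
           " (expected n-1, n, n+1)")
  }
  off <- sort(unique(unname(off)))
  if (!length(off) || !all(off %in% (-1L:1L)))
    stop("window members must form a non-empty subset of {N-1, N, N+1}")
  off
}

#' Windowed siRMSD around a modified position
#'
#' Scores the distortion at position N using any non-empty subset of the
#' N-1/N/N+1 nucleobases. Three combination rules are available for
#' multi-nucleotide windows:
#' \describe{
#'   \item{POOLED (default)}{the RMSD formula applied once over the union
#'     of all member-nucleotide heavy atoms; units stay Angstroms.}
#'   \item{SUM_RMSD}{sum over members of the per-nucleotide values
#'     (Angstroms).}
#'   \item{SUM_MSD}{sum over members of the per-nucleotide mean squared
#'     distances (squared Angstroms).}
#' }
#' Per-nucleotide values are always computed and returned alongside.
#'
#' @param modified,unmodified [GuideStructure-class] objects in the same
#'   coordinate frame.
#' @param position the modified position N (typically 2-8).
#' @param window window members, either integer offsets within -1..1 or
#'   labels such as `c("n-1", "n", "n+1")` / `"n-1,n,n+1"`. Member
#'   positions below 1 are dropped only if absent from the models; an
#'   explicit member missing from either model is an error.
#' @param mode `"POOLED"`, `"SUM_RMSD"` or `"SUM_MSD"`.
#' @return a [SiRmsdResult-class].
#' @examples
#' m <- makeGuideStructure("UACGGAUCA")
#' p <- perturbStructure(m, positions = 2:4, sd = 0.3, seed = 1)
#' sirmsdWindow(p$model, m, position = 3, window = "n-1,n,n+1")
#' @export
sirmsdWindow <- function(modified, unmodified, position,
                         window = c("n-1", "n", "n+1"),
                         mode = c("POOLED", "SUM_RMSD", "SUM_MSD")) {
  mode <- match.arg(toupper(mode[1L]), .SIRMSD_MODES)
  off <- .offsetsFromWindow(window)
  pos <- position + off
  if (any(pos < 1L))
    stop("window member position(s) below 1: ",
         paste(pos[pos < 1L], collapse = ", "))
  for (p in pos) {
    if (!p %in% guidePositions(modified))
      stop("position ", p, " absent from the modified model")
    if (!p %in% guidePositions(unmodified))
      stop("position ", p, " absent from the unmodified model")
  }
  perPair <- lapply(pos, function(p) {
    base <- residueAtoms(unmodified, p)$base[1L]
    sel <- list(.NUCLEOBASE_HEAVY[[base]])
    names(sel) <- p
    pairByName(modified, unmodified, sel)
  })
  perK <- vapply(perPair, pairCount, integer(1))
  perVal <- vapply(perPair, sirmsdSingle, numeric(1))
  names(perVal) <- pos
  value <- switch(mode,
    POOLED = sqrt(sum(perK * perVal^2) / sum(perK)),
    SUM_RMSD = sum(perVal),
    SUM_MSD = sum(perVal^2))
  new("SiRmsdResult", position = as.integer(position), members = off,
      mode = mode, value = value, K = as.integer(sum(perK)),
      perNucleotide = perVal)
}

## The seven window combinations, canonical order.
.WINDOW_COMBINATIONS <- list(
  "n-1" = -1L, "n" = 0L, "n+1" = 1L,
  "n-1/n" = c(-1L, 0L), "n-1/n+1" = c(-1L, 1L), "n/n+1" = c(0L, 1L),
  "n-1/n/n+1" = c(-1L, 0L, 1L))

#' Position profile of windowed siRMSD values
#'
#' Evaluates every window combination (N-1, N, N+1, N-1/N, N-1/N+1,
#' N/N+1, N-1/N/N+1) for every supplied (position, modification)
#' structure pair, producing the long table behind per-position
#' distortion profiles.
#'
#' @param modelPairs a list; each element a list with components
#'   `position` (modified position N), `modification` (code),
#'   `modified` and `unmodified` ([GuideStructure-class] objects).
#' @param modes combination modes to evaluate.
#' @return data.frame with columns `position`, `modification`,
#'   `combination`, `mode`, `sirmsd_A`, `K`, ordered by (position,
#'   modification, combination).
#' @export
profileScan <- function(modelPairs, modes = "POOLED") {
  modes <- vapply(modes, function(m) match.arg(toupper(m), .SIRMSD_MODES),
                  character(1))
  rows <- list()
  for (mp in modelPairs) {
    for (ci in seq_along(.WINDOW_COMBINATIONS)) {
      comb <- names(.WINDOW_COMBINATIONS)[ci]
      for (mode in modes) {
        res <- sirmsdWindow(mp$modified, mp$unmodified, mp$position,
                            window = .WINDOW_COMBINATIONS[[ci]],
                            mode = mode)
        rows[[length(rows) + 1L]] <- data.frame(
          position = mp$position, modification = mp$modification,
          combination = comb, mode = mode, sirmsd_A = res@value,
          K = res@K, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  comb_rank <- match(out$combination, names(.WINDOW_COMBINATIONS))
  out <- out[order(out$position, out$modification, comb_rank, out$mode), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise a SiRmsdResult as a JSON report
#'
#' @param x a [SiRmsdResult-class].
#' @param file optional output path; when NULL the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
sirmsdReportJSON <- function(x, file = NULL) {
  stopifnot(is(x, "SiRmsdResult"))
  obj <- list(position = x@position,
              window = names(.WINDOW_COMBINATIONS)[
                vapply(.WINDOW_COMBINATIONS, identical, logical(1),
                       x@members)],
              mode = x@mode, value = x@value, K = x@K,
              per_nucleotide = as.list(x@perNucleotide))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(file)) return(js)
  writeLines(js, file)
  invisible(js)
}
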