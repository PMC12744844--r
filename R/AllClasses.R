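## Central S4 containers. Atom records live in a plain data.frame slot
## (one row per atom) rather than one object per atom; validity methods
## enforce the invariants the downstream scoring relies on.

#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show slot
NULL

## closed vocabularies ------------------------------------------------------

.BASES <- c("A", "U", "G", "C", "T")
.MODIFICATIONS <- c("RNA", "DNA", "FLUORO", "MOE", "OME", "FA", "MTMM")
.SOURCES <- c("PDB", "XYZ_ANNOTATED", "SYNTHETIC")
.SIRMSD_MODES <- c("POOLED", "SUM_RMSD", "SUM_MSD")

.ATOM_COLS <- c("serial", "atom", "element", "x", "y", "z",
                "occupancy", "altLoc", "guidePosition", "base",
                "modification")

#' GuideStructure: atomic model of a guide-RNA fragment
#'
#' Holds the atoms of a (possibly chemically modified) guide-strand
#' fragment, grouped into residues indexed by 1-based guide position
#' counted from the 5' end. Coordinates are in Angstroms and are expected
#' to share one fixed reference frame (the Argonaute 2 frame for models
#' derived from AGO2-bound structures), because distortion scoring
#' compares coordinates directly without superposition.
#'
#' @slot modelId single string identifying the model.
#' @slot atoms data.frame with columns `serial`, `atom`, `element`, `x`,
#'   `y`, `z`, `occupancy`, `altLoc`, `guidePosition`, `base`,
#'   `modification`; one row per atom, ordered by guide position.
#' @slot source provenance: `"PDB"`, `"XYZ_ANNOTATED"` or `"SYNTHETIC"`.
#' @aliases GuideStructure
#' @exportClass GuideStructure
setClass("GuideStructure",
         representation(modelId = "character",
                        atoms = "data.frame",
                        source = "character"))

setValidity("GuideStructure", function(object) {
  msg <- character()
  at <- object@atoms
  if (length(object@modelId) != 1L || is.na(object@modelId))
    msg <- c(msg, "modelId must be a single non-NA string")
  if (!all(.ATOM_COLS %in% names(at)))
    msg <- c(msg, paste0("atoms is missing columns: ",
                         paste(setdiff(.ATOM_COLS, names(at)), collapse = ", ")))
  if (length(object@source) != 1L || !object@source %in% .SOURCES)
    msg <- c(msg, paste0("source must be one of ",
                         paste(.SOURCES, collapse = "/")))
  if (all(.ATOM_COLS %in% names(at)) && nrow(at) > 0L) {
    if (!all(is.finite(at$x) & is.finite(at$y) & is.finite(at$z)))
      msg <- c(msg, "all coordinates must be finite")
    if (!all(is.finite(at$occupancy) & at$occupancy >= 0 & at$occupancy <= 1))
      msg <- c(msg, "occupancy must lie in [0, 1]")
    if (!all(at$base %in% .BASES))
      msg <- c(msg, paste0("unrecognised base code(s): ",
                           paste(unique(setdiff(at$base, .BASES)), collapse = ", ")))
    if (!all(at$modification %in% .MODIFICATIONS))
      msg <- c(msg, paste0("unrecognised modification code(s): ",
                           paste(unique(setdiff(at$modification, .MODIFICATIONS)),
                                 collapse = ", ")))
    if (!all(at$guidePosition >= 1L))
      msg <- c(msg, "guide positions must be >= 1")
    if (is.unsorted(at$guidePosition))
      msg <- c(msg, "atoms must be ordered by guide position")
    key <- paste(at$guidePosition, at$atom)
    if (anyDuplicated(key))
      msg <- c(msg, paste0("duplicate (guidePosition, atom) pairs: ",
                           paste(unique(key[duplicated(key)]), collapse = ", ")))
    pb <- unique(at[, c("guidePosition", "base")])
    if (anyDuplicated(pb$guidePosition))
      msg <- c(msg, "a guide position is assigned more than one base")
  }
  if (length(msg)) msg else TRUE
})

#' AtomPairing: matched atoms between two structures
#'
#' Bijective pairing of selected atoms between a modified and an
#' unmodified model, matched by (guide position, atom name), with the
#' per-pair Euclidean distance delta in Angstroms measured in the shared
#' coordinate frame.
#'
#' @slot pairs data.frame with columns `guidePosition`, `atom`, `delta`.
#' @slot K integer, number of pairs (equals `nrow(pairs)`).
#' @aliases AtomPairing
#' @exportClass AtomPairing
setClass("AtomPairing",
         representation(pairs = "data.frame", K = "integer"))

setValidity("AtomPairing", function(object) {
  msg <- character()
  p <- object@pairs
  need <- c("guidePosition", "atom", "delta")
  if (!all(need %in% names(p)))
    msg <- c(msg, "pairs needs columns guidePosition, atom, delta")
  else {
    if (object@K != nrow(p)) msg <- c(msg, "K must equal nrow(pairs)")
    if (nrow(p) && !all(is.finite(p$delta) & p$delta >= 0))
      msg <- c(msg, "all deltas must be finite and >= 0")
    if (anyDuplicated(paste(p$guidePosition, p$atom)))
      msg <- c(msg, "pairing must be a bijection on (guidePosition, atom)")
  }
  if (length(msg)) msg else TRUE
})

#' SiRmsdResult: windowed distortion score
#'
#' @slot position integer, the modified position N.
#' @slot members integer offsets relative to N actually used
#'   (subset of -1, 0, 1).
#' @slot mode `"POOLED"`, `"SUM_RMSD"` or `"SUM_MSD"`.
#' @slot value the statistic (Angstroms; squared Angstroms for SUM_MSD).
#' @slot K total number of atom pairs used.
#' @slot perNucleotide named numeric, single-nucleotide siRMSD (Angstroms)
#'   keyed by absolute guide position.
#' @aliases SiRmsdResult
#' @exportClass SiRmsdResult
setClass("SiRmsdResult",
         representation(position = "integer", members = "integer",
                        mode = "character", value = "numeric",
                        K = "integer", perNucleotide = "numeric"))

setValidity("SiRmsdResult", function(object) {
  msg <- character()
  if (!object@mode %in% .SIRMSD_MODES)
    msg <- c(msg, paste0("mode must be one of ", paste(.SIRMSD_MODES, collapse = "/")))
  if (!length(object@members) || !all(object@members %in% (-1L:1L)))
    msg <- c(msg, "members must be a non-empty subset of {-1, 0, 1}")
  if (object@K <= 0L) msg <- c(msg, "K must be positive")
  if (!is.finite(object@value) || object@value < 0)
    msg <- c(msg, "value must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' SOAResult: substantial off-target activity
#'
#' Rescales the modified siRNA's relative off-target reporter activity
#' against the unmodified siRNA's: 0 means the modification leaves
#' off-target repression unchanged, 100 means it abolishes it (reporter
#' fully derepressed). Values are reported as computed, without clamping.
#'
#' @slot value SOA in percent.
#' @slot relModified,relUnmodified the relative luciferase activities (%)
#'   the value was computed from.
#' @aliases SOAResult
#' @exportClass SOAResult
setClass("SOAResult",
         representation(value = "numeric", relModified = "numeric",
                        relUnmodified = "numeric"))

#' IC50Result: bracketing log-interpolated IC50
#'
#' @slot estimable FALSE when the dose-response never crosses 50%
#'   inhibition; `ic50` is then NA.
#' @slot ic50 IC50 in the concentration units of the input.
#' @slot bracket named numeric (`A`, `B`, `C`, `D`): the bracketing
#'   concentrations A (inhibition < 50%) and B (> 50%) and their
#'   inhibitions D and C; NA for an exact 50% hit.
#' @aliases IC50Result
#' @exportClass IC50Result
setClass("IC50Result",
         representation(estimable = "logical", ic50 = "numeric",
                        bracket = "numeric"))

#' TmEstimate: melting temperature by the second-derivative method
#'
#' @slot estimable FALSE when the curve shows no melting transition.
#' @slot tm melting temperature, degrees Celsius.
#' @slot method fixed label `"second_derivative"`.
#' @slot smoothingWindow points in the local-quadratic smoothing window.
#' @aliases TmEstimate
#' @exportClass TmEstimate
setClass("TmEstimate",
         representation(estimable = "logical", tm = "numeric",
                        method = "character", smoothingWindow = "integer"))

#' OffTargetSummary: seed-match expression shift
#'
#' @slot meanL2fcSM,meanL2fcNonSM mean log2 fold change (treated/mock) of
#'   seed-matched and non-seed-matched transcripts.
#' @slot difference `meanL2fcSM - meanL2fcNonSM`.
#' @slot pWilcoxon two-sided Wilcoxon rank-sum p value for the group shift.
#' @slot nSM,nNonSM group sizes.
#' @slot ma per-transcript MA table (`transcript_id`, `A` = average log10
#'   intensity, `M` = log2 fold change, `sm`).
#' @slot cumulative cumulative-fraction table per group (`group`, `l2fc`,
#'   `fraction`).
#' @aliases OffTargetSummary
#' @exportClass OffTargetSummary
setClass("OffTargetSummary",
         representation(meanL2fcSM = "numeric", meanL2fcNonSM = "numeric",
                        difference = "numeric", pWilcoxon = "numeric",
                        nSM = "integer", nNonSM = "integer",
                        ma = "data.frame", cumulative = "data.frame"))

#' CorrelationReport: Pearson r with Fisher 95% CI
#'
#' @slot estimable FALSE when a variance is zero (undefined correlation).
#' @slot r sample Pearson correlation.
#' @slot n number of points.
#' @slot p two-sided p value from the t statistic on n - 2 df.
#' @slot ci95 numeric(2), Fisher z-transform confidence interval
#'   (NA below n = 4).
#' @aliases CorrelationReport
#' @exportClass CorrelationReport
setClass("CorrelationReport",
         representation(estimable = "logical", r = "numeric",
                        n = "integer", p = "numeric", ci95 = "numeric"))

setValidity("CorrelationReport", function(object) {
  msg <- character()
  if (object@estimable) {
    if (!is.finite(object@r) || abs(object@r) > 1 + 1e-12)
      msg <- c(msg, "r must lie in [-1, 1]")
    if (object@n >= 4L && all(is.finite(object@ci95))) {
      if (!(object@ci95[1] <= object@r + 1e-12 &&
            object@r <= object@ci95[2] + 1e-12))
        msg <- c(msg, "ci95 must contain r")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RegressionBand: least-squares fit with mean-response confidence band
#'
#' @slot slope,intercept ordinary least-squares coefficients.
#' @slot level confidence level of the band (default 0.95).
#' @slot band data.frame (`x`, `fit`, `lower`, `upper`) on a grid spanning
#'   the observed x range.
#' @aliases RegressionBand
#' @exportClass RegressionBand
setClass("RegressionBand",
         representation(slope = "numeric", intercept = "numeric",
                        level = "numeric", band = "data.frame"))

## show methods -------------------------------------------------------------

setMethod("show", "GuideStructure", function(object) {
  at <- object@atoms
  pos <- unique(at$guidePosition)
  cat("GuideStructure '", object@modelId, "' [", object@source, "]\n",
      sep = "")
  cat("  ", nrow(at), " atoms in ", length(pos), " residue(s), positions ",
      if (length(pos)) paste(range(pos), collapse = "-") else "-", "\n",
      sep = "")
  ri <- unique(at[, c("guidePosition", "base", "modification")])
  cat("  ", paste0(ri$base, ri$guidePosition,
                   ifelse(ri$modification == "RNA", "",
                          paste0("[", ri$modification, "]")),
                   collapse = " "), "\n", sep = "")
})

setMethod("show", "AtomPairing", function(object) {
  cat("AtomPairing with K =", object@K, "atom pairs\n")
  if (object@K) {
    cat("  delta range:",
        sprintf("%.4f - %.4f A", min(object@pairs$delta),
                max(object@pairs$delta)), "\n")
  }
})

setMethod("show", "SiRmsdResult", function(object) {
  mem <- paste(ifelse(object@members < 0, "N-1",
                      ifelse(object@members == 0, "N", "N+1")),
               collapse = "/")
  unit <- if (object@mode == "SUM_MSD") "A^2" else "A"
  cat(sprintf("siRMSD_%s at position %d [%s]: %.4f %s (K = %d)\n",
              mem, object@position, object@mode, object@value, unit,
              object@K))
  pn <- object@perNucleotide
  cat("  per nucleotide:",
      paste(sprintf("%s: %.4f", names(pn), pn), collapse = ", "), "\n")
})

setMethod("show", "SOAResult", function(object) {
  cat(sprintf("SOA = %.2f%% (modified %.2f%%, unmodified %.2f%%)\n",
              object@value, object@relModified, object@relUnmodified))
})

setMethod("show", "IC50Result", function(object) {
  if (!object@estimable)
    cat("IC50: not estimable (inhibition never crosses 50%)\n")
  else if (all(is.na(object@bracket)))
    cat(sprintf("IC50 = %.4g (exact 50%% inhibition at a tested concentration)\n",
                object@ic50))
  else
    cat(sprintf("IC50 = %.4g (bracket A = %.4g [%.1f%%], B = %.4g [%.1f%%])\n",
                object@ic50, object@bracket["A"], object@bracket["D"],
                object@bracket["B"], object@bracket["C"]))
})

setMethod("show", "TmEstimate", function(object) {
  if (!object@estimable)
    cat("Tm: not estimable (no melting transition detected)\n")
  else
    cat(sprintf("Tm = %.2f degC (%s, smoothing window %d points)\n",
                object@tm, object@method, object@smoothingWindow))
})

setMethod("show", "OffTargetSummary", function(object) {
  cat(sprintf(paste0("Seed-match expression shift: %.4f log2 units\n",
                     "  SM mean %.4f (n = %d) vs non-SM mean %.4f (n = %d)\n",
                     "  Wilcoxon rank-sum p = %.3g\n"),
              object@difference, object@meanL2fcSM, object@nSM,
              object@meanL2fcNonSM, object@nNonSM, object@pWilcoxon))
})

setMethod("show", "CorrelationReport", function(object) {
  if (!object@estimable)
    cat("Pearson correlation: undefined (zero variance)\n")
  else
    cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g, 95%% CI %.3f to %.3f)\n",
                object@r, object@n, object@p, object@ci95[1], object@ci95[2]))
})

setMethod("show", "RegressionBand", function(object) {
  cat(sprintf("Linear fit y = %.4g x + %.4g with %.0f%% mean-response band (%d grid points)\n",
              object@slope, object@intercept, 100 * object@level,
              nrow(object@band)))
})
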