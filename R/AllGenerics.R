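## Accessor generics. Slot access from user code is discouraged; these are
## the supported surface.

#' @describeIn GuideStructure model identifier.
#' @param x,object a `GuideStructure` (or other object as documented).
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @describeIn GuideStructure atom table (one row per atom).
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @describeIn GuideStructure provenance label.
#' @export
setGeneric("structureSource", function(x) standardGeneric("structureSource"))

#' @describeIn GuideStructure sorted unique guide positions present.
#' @export
setGeneric("guidePositions", function(x) standardGeneric("guidePositions"))

#' @describeIn GuideStructure atoms of one residue.
#' @param position 1-based guide position.
#' @export
setGeneric("residueAtoms",
           function(x, position) standardGeneric("residueAtoms"))

#' @describeIn AtomPairing the pair table (`guidePosition`, `atom`, `delta`).
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @describeIn AtomPairing number of atom pairs K.
#' @export
setGeneric("pairCount", function(x) standardGeneric("pairCount"))

#' Numeric value carried by a result object
#'
#' Single headline number of a result: the siRMSD statistic, the SOA
#' percentage, the IC50, the Tm, the SM-vs-non-SM log2 shift, or the
#' Pearson r, depending on the class.
#'
#' @param x a result object.
#' @return a numeric scalar (NA when the result is flagged not estimable).
#' @export
setGeneric("resultValue", function(x) standardGeneric("resultValue"))

#' Is a result estimable?
#'
#' Sentinel accessor for operations that can fail for scientific rather
#' than programming reasons (no 50% crossing, no melting transition, zero
#' variance).
#'
#' @param x a result object.
#' @return logical scalar.
#' @export
setGeneric("isEstimable", function(x) standardGeneric("isEstimable"))

#' @describeIn SiRmsdResult per-nucleotide siRMSD values (named by
#'   absolute guide position).
#' @param x a `SiRmsdResult`.
#' @export
setGeneric("perNucleotide", function(x) standardGeneric("perNucleotide"))

## methods ------------------------------------------------------------------

#' @export
setMethod("modelId", "GuideStructure", function(x) x@modelId)
#' @export
setMethod("atomTable", "GuideStructure", function(x) x@atoms)
#' @export
setMethod("structureSource", "GuideStructure", function(x) x@source)
#' @export
setMethod("guidePositions", "GuideStructure",
          function(x) sort(unique(x@atoms$guidePosition)))
#' @export
setMethod("residueAtoms", "GuideStructure", function(x, position) {
  stopifnot(length(position) == 1L)
  x@atoms[x@atoms$guidePosition == position, , drop = FALSE]
})

#' @export
setMethod("pairTable", "AtomPairing", function(x) x@pairs)
#' @export
setMethod("pairCount", "AtomPairing", function(x) x@K)

#' @export
setMethod("resultValue", "SiRmsdResult", function(x) x@value)
#' @export
setMethod("resultValue", "SOAResult", function(x) x@value)
#' @export
setMethod("resultValue", "IC50Result",
          function(x) if (x@estimable) x@ic50 else NA_real_)
#' @export
setMethod("resultValue", "TmEstimate",
          function(x) if (x@estimable) x@tm else NA_real_)
#' @export
setMethod("resultValue", "OffTargetSummary", function(x) x@difference)
#' @export
setMethod("resultValue", "CorrelationReport",
          function(x) if (x@estimable) x@r else NA_real_)

#' @export
setMethod("isEstimable", "IC50Result", function(x) x@estimable)
#' @export
setMethod("isEstimable", "TmEstimate", function(x) x@estimable)
#' @export
setMethod("isEstimable", "CorrelationReport", function(x) x@estimable)

#' @export
setMethod("perNucleotide", "SiRmsdResult", function(x) x@perNucleotide)
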