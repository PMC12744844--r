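## Seed-mediated off-target analysis of expression data: QC-flag
## filtering, quantile normalisation, classification of transcripts by
## presence of the seed-complementary 7-mer in their 3'UTR, and the
## SM-vs-non-SM mean log2 fold-change shift with a Wilcoxon rank-sum
## test, plus MA and cumulative-fraction tables.

#' Seed of a guide strand
#'
#' Guide-strand nucleotides 2-8 counted from the 5' end -- the seed
#' region whose pairing with a 3'UTR drives off-target repression.
#'
#' @param guide guide-strand sequence (RNA or DNA alphabet), length >= 8.
#' @return the 7-mer seed, uppercase, as supplied (U/T not re-encoded).
#' @examples
#' seedOf("UACGGAUCAAU")  # "ACGGAUC"
#' @export
seedOf <- function(guide) {
  guide <- toupper(guide)
  if (nchar(guide) < 8L)
    stop("guide must be at least 8 nt to have a seed (positions 2-8)")
  substr(guide, 2L, 8L)
}

#' Classify transcripts as seed-matched (SM)
#'
#' A transcript is SM iff the DNA reverse complement of the 7-nt seed
#' occurs as an exact substring of its 3'UTR. No G:U wobble and no
#' mismatches are tolerated. U/T encoding of both seed and UTRs is
#' normalised before matching.
#'
#' @param utr3 character vector of 3'UTR sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param seed the 7-mer seed (RNA or DNA alphabet).
#' @return logical vector, one flag per transcript.
#' @examples
#' classifySM(c("AAGATCCGTAA", "AAAAAA", ""), "ACGGAUC")
#' @export
classifySM <- function(utr3, seed) {
  seed <- chartr("Uu", "Tt", toupper(seed))
  if (nchar(seed) != 7L) stop("seed must be exactly 7 nt")
  target <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seed)))
  utr <- chartr("Uu", "Tt", toupper(as.character(utr3)))
  grepl(target, utr, fixed = TRUE)
}

.QC_FLAGS <- c(ControlType = 0L, gIsPosAndSignif = 1L,
               gIsFeatNonUnifOL = 0L, gIsWellAboveBG = 1L,
               gIsSaturated = 0L, gIsFeatPopnOL = 0L)

#' Array QC filtering
#'
#' A record survives iff all six feature-extraction QC conditions hold
#' (ControlType = 0, gIsPosAndSignif = 1, gIsFeatNonUnifOL = 0,
#' gIsWellAboveBG = 1, gIsSaturated = 0, gIsFeatPopnOL = 0) and its
#' identifier matches the configured systematic-name pattern.
#'
#' @param records data.frame with a `transcript_id` column and the six
#'   QC-flag columns.
#' @param idPattern regular expression the identifier must match;
#'   defaults to RefSeq mRNA accessions.
#' @return the surviving rows of `records`.
#' @export
qcFilter <- function(records, idPattern = "^NM_") {
  missing <- setdiff(c("transcript_id", names(.QC_FLAGS)), names(records))
  if (length(missing))
    stop("QC record table is missing column(s): ",
         paste(missing, collapse = ", "))
  keep <- grepl(idPattern, records$transcript_id)
  for (flag in names(.QC_FLAGS))
    keep <- keep & (records[[flag]] == .QC_FLAGS[[flag]])
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantile normalisation of an expression matrix
#'
#' Forces every column's distribution to the across-column mean of sorted
#' values while preserving within-column ranks; ties are assigned the
#' mean of the tied quantile targets. Idempotent.
#'
#' @param mat numeric matrix (transcripts x samples) of positive signal
#'   intensities, no missing values.
#' @return the normalised matrix, same dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("expression matrix must have no missing values")
  if (any(mat <= 0)) stop("signal intensities must be positive")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' SM vs non-SM expression shift
#'
#' Computes per-transcript log2 fold changes treated/mock on the
#' (quantile-normalised) intensity scale, the mean log2 fold change of
#' seed-matched and non-seed-matched transcripts and their difference,
#' and a two-sided Wilcoxon rank-sum p value for the group shift (exact
#' enumeration when the larger group has <= 20 transcripts, normal
#' approximation with continuity correction otherwise). Also returns the
#' per-transcript MA table (M = log2 fold change, A = average log10
#' intensity) and per-group cumulative-fraction curves.
#'
#' @param mat numeric matrix (transcripts x samples), positive values;
#'   row names are transcript identifiers.
#' @param smFlags logical vector, one per transcript (see
#'   [classifySM()]).
#' @param treated,mock column names or indices of the treated and mock
#'   samples.
#' @return an [OffTargetSummary-class].
#' @export
offtargetMagnitude <- function(mat, smFlags, treated, mock) {
  mat <- as.matrix(mat)
  stopifnot(length(smFlags) == nrow(mat))
  for (col in list(treated, mock)) {
    ok <- if (is.character(col)) col %in% colnames(mat)
          else col >= 1 && col <= ncol(mat)
    if (!ok) stop("sample column not present in the matrix: ", col)
  }
  if (!any(smFlags)) stop("no seed-matched transcripts in the input")
  if (all(smFlags)) stop("no non-seed-matched transcripts in the input")
  tv <- mat[, treated]
  mv <- mat[, mock]
  if (any(tv <= 0) || any(mv <= 0))
    stop("signal intensities must be positive")
  M <- log2(tv / mv)
  A <- (log10(tv) + log10(mv)) / 2
  sm <- as.logical(smFlags)
  ## exact enumeration for small groups (impossible with ties), normal
  ## approximation with continuity correction otherwise
  exact <- max(sum(sm), sum(!sm)) <= 20L && !anyDuplicated(M)
  wt <- stats::wilcox.test(M[sm], M[!sm], alternative = "two.sided",
                           exact = exact, correct = TRUE)
  ids <- if (is.null(rownames(mat))) as.character(seq_len(nrow(mat)))
         else rownames(mat)
  cum <- function(v, lab) {
    v <- sort(v)
    data.frame(group = lab, l2fc = v,
               fraction = seq_along(v) / length(v))
  }
  new("OffTargetSummary",
      meanL2fcSM = mean(M[sm]), meanL2fcNonSM = mean(M[!sm]),
      difference = mean(M[sm]) - mean(M[!sm]),
      pWilcoxon = wt$p.value,
      nSM = sum(sm), nNonSM = sum(!sm),
      ma = data.frame(transcript_id = ids, A = A, M = M, sm = sm,
                      stringsAsFactors = FALSE),
      cumulative = rbind(cum(M[sm], "SM"), cum(M[!sm], "non-SM")))
}
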