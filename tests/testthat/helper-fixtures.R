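# Shared fixtures and independent oracles. The oracles here are written
# from first principles (explicit loops, enumeration) so they stay
# independent of the vectorised implementation paths they check.

# Minimal hand-built structure: df needs atom, element, x, y, z,
# guidePosition, base; modification defaults to RNA.
toyStructure <- function(df, modelId = "toy") {
  at <- data.frame(
    serial = seq_len(nrow(df)),
    atom = df$atom,
    element = if ("element" %in% names(df)) df$element else
      substr(df$atom, 1, 1),
    x = df$x, y = df$y, z = df$z,
    occupancy = 1, altLoc = "",
    guidePosition = df$guidePosition,
    base = if ("base" %in% names(df)) df$base else "U",
    modification = if ("modification" %in% names(df)) df$modification
      else "RNA",
    stringsAsFactors = FALSE)
  new("GuideStructure", modelId = modelId,
      atoms = at[order(at$guidePosition), ], source = "SYNTHETIC")
}

# Brute-force RMSD oracle: explicit double loop over atoms, no
# vectorisation; matches by (position, atom name).
bruteSirmsd <- function(modTable, unmodTable) {
  total <- 0
  K <- 0L
  for (i in seq_len(nrow(modTable))) {
    for (j in seq_len(nrow(unmodTable))) {
      if (modTable$guidePosition[i] == unmodTable$guidePosition[j] &&
          modTable$atom[i] == unmodTable$atom[j]) {
        dd <- (modTable$x[i] - unmodTable$x[j])^2 +
              (modTable$y[i] - unmodTable$y[j])^2 +
              (modTable$z[i] - unmodTable$z[j])^2
        total <- total + dd
        K <- K + 1L
      }
    }
  }
  sqrt(total / K)
}

# Random paired toy structures (same atom names, independent coordinates).
randomToyPair <- function(nAtoms, seed) {
  set.seed(seed)
  names <- paste0("X", seq_len(nAtoms))
  mk <- function() toyStructure(data.frame(
    atom = names, element = "C",
    x = rnorm(nAtoms), y = rnorm(nAtoms), z = rnorm(nAtoms),
    guidePosition = 1L))
  list(a = mk(), b = mk())
}

# Pearson r from the definition: centred cross-products over sd product.
pearsonOracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (no ties expected).
wilcoxExactOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  idx <- utils::combn(n1 + n2, n1)
  Us <- apply(idx, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
  pLow <- mean(Us <= W)
  pHigh <- mean(Us >= W)
  min(1, 2 * min(pLow, pHigh))
}

# Fixed-column PDB ATOM line builder for parser tests.
pdbLine <- function(serial = 1L, name = "N1", altLoc = " ",
                    resName = "A", resSeq = 2L, iCode = " ",
                    x = 0, y = 0, z = 0, occ = 1, element = "N") {
  sprintf("ATOM  %5d %-4s%1s%3s A%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, altLoc, resName, resSeq, iCode, x, y, z, occ, 0,
          element)
}
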