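## Steric extent of a 2'-ribose modification: the distance from the
## ribose C2' carbon to the farthest atom of the 2' substituent,
## hydrogens included. Coordinate files carry no connectivity, so bonds
## are inferred from covalent radii and the substituent is identified by
## graph traversal from C2' that is forbidden from re-entering the sugar
## ring.

## Single-bond covalent radii (Angstroms), Cordero et al. consensus values.
.COVALENT_RADII <- c(H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66,
                     F = 0.57, P = 1.07, S = 1.05)

#' Infer covalent bonds within one residue
#'
#' Two atoms are bonded iff their distance is below the sum of their
#' covalent radii plus a tolerance. The default tolerance of 0.45
#' Angstroms is robust for quantum-chemistry-optimised geometries without
#' hallucinating 1-3 contacts.
#'
#' @param x a [GuideStructure-class].
#' @param position guide position of the residue.
#' @param tolerance Angstroms added to the summed covalent radii.
#' @return data.frame of bonds with columns `atom1`, `atom2`, `length`
#'   (each bond listed once, `atom1` < `atom2` lexicographically).
#' @export
inferBonds <- function(x, position, tolerance = 0.45) {
  res <- residueAtoms(x, position)
  if (!nrow(res)) stop("no residue at guide position ", position)
  unknown <- setdiff(unique(res$element), names(.COVALENT_RADII))
  if (length(unknown))
    stop("unknown element(s), no tabulated covalent radius: ",
         paste(unknown, collapse = ", "))
  xyz <- as.matrix(res[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  r <- .COVALENT_RADII[res$element]
  cutoff <- outer(r, r, `+`) + tolerance
  hit <- which(d < cutoff & upper.tri(d), arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(atom1 = character(), atom2 = character(),
                      length = numeric()))
  a1 <- res$atom[hit[, 1L]]
  a2 <- res$atom[hit[, 2L]]
  swap <- a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  out <- data.frame(atom1 = a1, atom2 = a2,
                    length = d[hit], stringsAsFactors = FALSE)
  out[order(out$atom1, out$atom2), , drop = FALSE]
}

.BACKBONE_ATOMS <- c("P", "OP1", "OP2", "O5'", "O3'")

#' Atoms of the 2' substituent
#'
#' Breadth-first traversal of the inferred bond graph from C2', with the
#' ring neighbours C1' and C3' (and everything reachable only through
#' them) excluded. Hydrogens directly on C2' are included -- for a
#' 2'-deoxy residue they are the entire substituent. Reaching the
#' phosphate backbone indicates a corrupted bond graph and is an error.
#'
#' @param x a [GuideStructure-class].
#' @param position guide position of the residue.
#' @param tolerance bond-inference tolerance, Angstroms.
#' @return list with components `anchor` (the C2' atom row) and `atoms`
#'   (data.frame of substituent atom rows).
#' @export
substituentAtoms <- function(x, position, tolerance = 0.45) {
  res <- residueAtoms(x, position)
  if (!"C2'" %in% res$atom)
    stop("residue at position ", position, " has no C2' atom")
  bonds <- inferBonds(x, position, tolerance)
  adj <- split(c(bonds$atom2, bonds$atom1), c(bonds$atom1, bonds$atom2))
  blocked <- c("C1'", "C3'")
  seen <- "C2'"
  frontier <- setdiff(adj[["C2'"]], blocked)
  reached <- character()
  while (length(frontier)) {
    reached <- c(reached, frontier)
    seen <- c(seen, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, c(seen, blocked))
  }
  if (any(reached %in% .BACKBONE_ATOMS))
    stop("substituent traversal from C2' reached the phosphate backbone (",
         paste(intersect(reached, .BACKBONE_ATOMS), collapse = ", "),
         "); bond graph is inconsistent")
  list(anchor = res[res$atom == "C2'", , drop = FALSE],
       atoms = res[match(sort(reached), res$atom), , drop = FALSE])
}

#' Steric extent of a 2'-ribose modification
#'
#' The maximum Euclidean distance from the ribose C2' carbon to any atom
#' of the 2' substituent (hydrogens included). This anchored extent is
#' the size measure that orders the modification chemistries
#' DNA < 2'-fluoro < 2'-OH < 2'-OMe < 2'-FA < 2'-MOE < 2'-MTMM.
#'
#' @param x a [GuideStructure-class].
#' @param position guide position of the residue.
#' @param tolerance bond-inference tolerance, Angstroms.
#' @return list with components `modification` (code), `extent`
#'   (Angstroms), `farthest_atom` (atom name).
#' @examples
#' m <- makeGuideStructure("UACGGAUCA",
#'                         modifications = c("2" = "FLUORO"))
#' modificationExtent(m, 2)
#' @export
modificationExtent <- function(x, position, tolerance = 0.45) {
  sub <- substituentAtoms(x, position, tolerance)
  if (!nrow(sub$atoms))
    stop("empty 2' substituent at position ", position)
  a <- as.numeric(sub$anchor[1L, c("x", "y", "z")])
  d <- sqrt((sub$atoms$x - a[1L])^2 + (sub$atoms$y - a[2L])^2 +
            (sub$atoms$z - a[3L])^2)
  i <- which.max(d)
  list(modification = sub$atoms$modification[1L],
       extent = d[i], farthest_atom = sub$atoms$atom[i])
}
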