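## Reading, validating and indexing guide-RNA structure coordinates.
## Two on-disk forms are supported: fixed-column PDB records, and bare
## element-x-y-z coordinate blocks accompanied by an annotation table that
## assigns each row to (guide position, base, modification, atom name) --
## the bridge for quantum-chemistry coordinate listings that carry no
## residue labels.

.KNOWN_ELEMENTS <- c("H", "D", "C", "N", "O", "F", "P", "S")

## Atom-name normalisation: PDB dialects write primes as asterisks, and
## legacy thymine methyl C5M is accepted as an alias of C7.
.normalizeAtomName <- function(name) {
  x <- gsub("\\*", "'", trimws(name))
  x[x == "C5M"] <- "C7"
  x
}

.elementFromName <- function(name) {
  stripped <- sub("^[0-9]+", "", trimws(name))
  el <- toupper(substr(stripped, 1L, 1L))
  bad <- !el %in% .KNOWN_ELEMENTS
  if (any(bad))
    stop("cannot infer element from atom name(s): ",
         paste(unique(name[bad]), collapse = ", "))
  el
}

## Base-specific nucleobase heavy-atom sets, standard PDB nomenclature,
## canonical order (ring then exocyclic substituents).
.NUCLEOBASE_HEAVY <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "N6"),
  G = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6", "O6", "N2"),
  C = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  U = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
  T = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6"))

.newGuideStructure <- function(modelId, atoms, source) {
  atoms$atom <- .normalizeAtomName(atoms$atom)
  atoms <- atoms[order(atoms$guidePosition), , drop = FALSE]
  rownames(atoms) <- NULL
  new("GuideStructure", modelId = modelId, atoms = atoms, source = source)
}

#' Read a fixed-column PDB file into a GuideStructure
#'
#' Parses ATOM/HETATM records. Residue sequence numbers are taken as
#' 1-based guide positions. Alternate-location duplicates are resolved by
#' keeping the highest-occupancy copy (ties broken by the lexicographically
#' smallest alt-loc code); hydrogens are retained (atom selection happens
#' downstream). Files with insertion codes are rejected rather than
#' guessed at, to avoid silently misindexing residues.
#'
#' @param file path to a PDB file, or a character vector of its lines.
#' @param modifications optional named character vector mapping guide
#'   positions to modification codes (`"RNA"`, `"DNA"`, `"FLUORO"`,
#'   `"MOE"`, `"OME"`, `"FA"`, `"MTMM"`); unlisted positions default to
#'   `"RNA"` (or `"DNA"` for deoxy residue names).
#' @param modelId model identifier; defaults to the file name.
#' @return a [GuideStructure-class].
#' @examples
#' m <- makeGuideStructure("UACGGAUCA")
#' f <- tempfile(fileext = ".pdb")
#' writeStructurePDB(m, f)
#' readPDB(f)
#' @export
readPDB <- function(file, modifications = NULL, modelId = NULL) {
  if (length(file) == 1L && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(modelId)) modelId <- basename(file)
  } else {
    lines <- file
    if (is.null(modelId)) modelId <- "pdb"
  }
  sel <- which(substr(lines, 1L, 6L) %in% c("ATOM  ", "HETATM"))
  if (!length(sel)) stop("no ATOM/HETATM records found")
  fld <- function(ln, a, b) substr(ln, a, b)
  recs <- lines[sel]
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed fixed-column PDB record (", what, ") at line ",
           sel[bad[1L]], ": '", trimws(recs[bad[1L]]), "'")
    v
  }
  icode <- trimws(fld(recs, 27L, 27L))
  if (any(icode != ""))
    stop("insertion codes are not supported (first at line ",
         sel[which(icode != "")[1L]], ")")
  atoms <- data.frame(
    serial = as.integer(num(fld(recs, 7L, 11L), "serial")),
    atom = .normalizeAtomName(fld(recs, 13L, 16L)),
    element = trimws(fld(recs, 77L, 78L)),
    x = num(fld(recs, 31L, 38L), "x"),
    y = num(fld(recs, 39L, 46L), "y"),
    z = num(fld(recs, 47L, 54L), "z"),
    occupancy = num(ifelse(trimws(fld(recs, 55L, 60L)) == "", "1",
                           fld(recs, 55L, 60L)), "occupancy"),
    altLoc = trimws(fld(recs, 17L, 17L)),
    resName = trimws(fld(recs, 18L, 20L)),
    guidePosition = as.integer(num(fld(recs, 23L, 26L), "residue number")),
    stringsAsFactors = FALSE)
  noel <- atoms$element == ""
  if (any(noel)) atoms$element[noel] <- .elementFromName(atoms$atom[noel])
  atoms$element <- toupper(atoms$element)

  ## alt-loc resolution: highest occupancy, ties to smallest code;
  ## record order otherwise preserved
  atoms$.ridx <- seq_len(nrow(atoms))
  key <- paste(atoms$guidePosition, atoms$atom)
  ord <- order(key, -atoms$occupancy, atoms$altLoc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$guidePosition, atoms$atom)), ,
                 drop = FALSE]
  atoms <- atoms[order(atoms$.ridx), , drop = FALSE]
  atoms$.ridx <- NULL

  base <- .baseFromResName(atoms$resName)
  mod <- ifelse(startsWith(atoms$resName, "D"), "DNA", "RNA")
  if (!is.null(modifications)) {
    idx <- match(as.character(atoms$guidePosition), names(modifications))
    mod[!is.na(idx)] <- unname(modifications[idx[!is.na(idx)]])
  }
  atoms$base <- base
  atoms$modification <- mod
  atoms$resName <- NULL
  .newGuideStructure(modelId, atoms, "PDB")
}

.baseFromResName <- function(resName) {
  map <- c(A = "A", U = "U", G = "G", C = "C", T = "T",
           RA = "A", RU = "U", RG = "G", RC = "C",
           DA = "A", DT = "T", DG = "G", DC = "C", DU = "U",
           ADE = "A", URA = "U", GUA = "G", CYT = "C", THY = "T")
  b <- map[resName]
  if (anyNA(b))
    stop("unrecognised residue name(s): ",
         paste(unique(resName[is.na(b)]), collapse = ", "))
  unname(b)
}

#' Read an annotated element-x-y-z coordinate block
#'
#' Quantum-chemistry coordinate listings give bare element/x/y/z rows with
#' no residue information; a curated annotation table (built by inspection
#' of the listing) supplies, row by row, the guide position, base,
#' modification and atom name. Row counts must agree, and the element
#' implied by each mapped atom name must agree with the coordinate row's
#' element.
#'
#' @param coordsFile whitespace-delimited file with columns element, x, y,
#'   z (an optional header line is detected and skipped); alternatively a
#'   data.frame with those columns.
#' @param mapFile TSV with header columns `guide_position`, `base`,
#'   `modification`, `atom_name`; alternatively a data.frame.
#' @param modelId model identifier.
#' @return a [GuideStructure-class] with source `"XYZ_ANNOTATED"`.
#' @export
readAnnotatedXYZ <- function(coordsFile, mapFile, modelId = "annotated_xyz") {
  if (is.data.frame(coordsFile)) {
    xyz <- coordsFile
    names(xyz)[1:4] <- c("element", "x", "y", "z")
  } else {
    first <- utils::read.table(coordsFile, nrows = 1L,
                               stringsAsFactors = FALSE)
    skip <- if (ncol(first) >= 2L &&
                is.na(suppressWarnings(as.numeric(first[[2L]])))) 1L else 0L
    xyz <- utils::read.table(coordsFile, skip = skip,
                             col.names = c("element", "x", "y", "z"),
                             stringsAsFactors = FALSE)
  }
  map <- if (is.data.frame(mapFile)) mapFile else
    utils::read.delim(mapFile, stringsAsFactors = FALSE)
  need <- c("guide_position", "base", "modification", "atom_name")
  if (!all(need %in% names(map)))
    stop("annotation table is missing column(s): ",
         paste(setdiff(need, names(map)), collapse = ", "))
  if (nrow(xyz) != nrow(map))
    stop("row-count mismatch: ", nrow(xyz), " coordinate rows vs ",
         nrow(map), " annotation rows")
  name <- .normalizeAtomName(map$atom_name)
  implied <- .elementFromName(name)
  got <- toupper(trimws(xyz$element))
  bad <- which(implied != got)
  if (length(bad))
    stop("element disagreement at annotation row ", bad[1L], ": atom '",
         name[bad[1L]], "' implies ", implied[bad[1L]],
         " but coordinates give ", got[bad[1L]])
  atoms <- data.frame(
    serial = seq_len(nrow(xyz)),
    atom = name,
    element = got,
    x = as.numeric(xyz$x), y = as.numeric(xyz$y), z = as.numeric(xyz$z),
    occupancy = 1, altLoc = "",
    guidePosition = as.integer(map$guide_position),
    base = toupper(map$base),
    modification = toupper(map$modification),
    stringsAsFactors = FALSE)
  .newGuideStructure(modelId, atoms, "XYZ_ANNOTATED")
}

#' Nucleobase heavy atoms of one residue
#'
#' Returns exactly the base-specific heavy-atom set (ring plus exocyclic
#' substituents of the base; no sugar, no phosphate, no hydrogens) in
#' canonical name order. These are the only atoms that ever enter siRMSD.
#'
#' @param x a [GuideStructure-class].
#' @param position guide position of the residue.
#' @return data.frame of atom rows in canonical order.
#' @examples
#' m <- makeGuideStructure("UACGGAUCA")
#' nrow(nucleobaseHeavyAtoms(m, 2))  # adenine: 10 heavy atoms
#' @export
nucleobaseHeavyAtoms <- function(x, position) {
  res <- residueAtoms(x, position)
  if (!nrow(res))
    stop("no residue at guide position ", position)
  base <- res$base[1L]
  want <- .NUCLEOBASE_HEAVY[[base]]
  idx <- match(want, res$atom)
  if (anyNA(idx))
    stop("incomplete ", base, " residue at position ", position,
         ": missing nucleobase atom(s) ",
         paste(want[is.na(idx)], collapse = ", "))
  out <- res[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair atoms between a modified and an unmodified structure
#'
#' Matches atoms by (guide position, atom name) and records the per-pair
#' Euclidean distance delta in the shared coordinate frame. No
#' superposition is applied by default: models derived from
#' protein-anchored optimisations share the protein frame, and the
#' distortion statistic is frame-difference sensitive by construction. An
#' explicit Kabsch superposition is available for exploratory use.
#'
#' @param modified,unmodified [GuideStructure-class] objects.
#' @param selection named list mapping guide positions (names) to atom-name
#'   character vectors; default: the nucleobase heavy atoms of every
#'   position the two models share.
#' @param superpose if TRUE, least-squares superpose the selected atoms of
#'   `modified` onto `unmodified` (Kabsch) before measuring distances.
#'   Off by default.
#' @return an [AtomPairing-class].
#' @examples
#' m <- makeGuideStructure("UACGGAUCA")
#' p <- pairByName(m, m)
#' max(pairTable(p)$delta)  # identical models: all deltas zero
#' @export
pairByName <- function(modified, unmodified, selection = NULL,
                       superpose = FALSE) {
  if (is.null(selection)) {
    pos <- intersect(guidePositions(modified), guidePositions(unmodified))
    if (!length(pos)) stop("models share no guide positions")
    selection <- lapply(pos, function(p) {
      base <- residueAtoms(unmodified, p)$base[1L]
      .NUCLEOBASE_HEAVY[[base]]
    })
    names(selection) <- pos
  }
  sel <- data.frame(
    guidePosition = rep(as.integer(names(selection)),
                        lengths(selection)),
    atom = .normalizeAtomName(unlist(selection, use.names = FALSE)),
    stringsAsFactors = FALSE)
  grab <- function(model, label) {
    at <- atomTable(model)
    idx <- match(paste(sel$guidePosition, sel$atom),
                 paste(at$guidePosition, at$atom))
    if (anyNA(idx)) {
      orph <- paste0(sel$guidePosition, ":", sel$atom)[is.na(idx)]
      stop("atoms missing from the ", label, " model: ",
           paste(orph, collapse = ", "))
    }
    as.matrix(at[idx, c("x", "y", "z")])
  }
  A <- grab(modified, "modified")
  B <- grab(unmodified, "unmodified")
  if (superpose) A <- .kabschAlign(A, B)
  delta <- sqrt(rowSums((A - B)^2))
  pairs <- data.frame(guidePosition = sel$guidePosition, atom = sel$atom,
                      delta = delta, stringsAsFactors = FALSE)
  new("AtomPairing", pairs = pairs, K = nrow(pairs))
}

## Kabsch least-squares superposition of A onto B (row-matched coordinates)
.kabschAlign <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  s <- svd(crossprod(A0, B0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(A0 %*% t(R), 2L, cb, `+`)
}

## ---- writers -------------------------------------------------------------

.PDB_RESNAME <- function(base, modification)
  ifelse(modification == "DNA", paste0("D", base), base)

#' Write a GuideStructure as fixed-column PDB
#'
#' @param x a [GuideStructure-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeStructurePDB <- function(x, file) {
  at <- atomTable(x)
  ## PDB names with a prime are left-aligned from column 14 by convention
  name4 <- sprintf("%-4s", substr(at$atom, 1L, 4L))
  lines <- sprintf(
    "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), name4, .PDB_RESNAME(at$base, at$modification),
    at$guidePosition, at$x, at$y, at$z, at$occupancy, 0, at$element)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Write a GuideStructure as an annotated XYZ pair
#'
#' Writes the coordinate block (element x y z) and the row-aligned
#' annotation TSV that [readAnnotatedXYZ()] consumes.
#'
#' @param x a [GuideStructure-class].
#' @param coordsFile,mapFile output paths.
#' @return `c(coordsFile, mapFile)`, invisibly.
#' @export
writeStructureXYZ <- function(x, coordsFile, mapFile) {
  at <- atomTable(x)
  writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                     at$element, at$x, at$y, at$z), coordsFile)
  map <- data.frame(guide_position = at$guidePosition, base = at$base,
                    modification = at$modification, atom_name = at$atom)
  utils::write.table(map, mapFile, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(coordsFile, mapFile))
}

#' Dump a GuideStructure as TSV
#'
#' @param x a [GuideStructure-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeStructureTSV <- function(x, file) {
  at <- atomTable(x)[, c("guidePosition", "atom", "element",
                         "x", "y", "z")]
  names(at)[1L] <- "guide_position"
  names(at)[2L] <- "atom_name"
  utils::write.table(at, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Rigidly translate a structure
#'
#' @param x a [GuideStructure-class].
#' @param shift numeric(3) displacement in Angstroms.
#' @return the translated [GuideStructure-class].
#' @export
translateStructure <- function(x, shift) {
  stopifnot(length(shift) == 3L, all(is.finite(shift)))
  at <- atomTable(x)
  at$x <- at$x + shift[1L]
  at$y <- at$y + shift[2L]
  at$z <- at$z + shift[3L]
  .newGuideStructure(modelId(x), at, structureSource(x))
}
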