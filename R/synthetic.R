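## Synthetic-fixture generators: every input the analysis modules consume
## can be produced here with known ground truth -- idealized helical
## guide-RNA coordinates with standard atom names and declared bond
## topology, perturbed copies with analytically known distortion,
## reporter triplicates with multiplicative noise, two-state melting
## curves, and expression matrices with a planted seed-match down-shift.
## All generators are pure functions of (parameters, seed); no global
## random state leaks.
##
## The helical models are idealized stand-ins, not physically accurate
## A-form RNA: the distortion statistic depends only on displacement
## fields between two models sharing a frame, so geometric realism is
## unnecessary. Bond lengths and angles follow standard small-molecule
## values so that covalent-bond inference recovers the declared topology.

## ---- internal: seeds and linear algebra ----------------------------------

.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = genv)), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

.unitv <- function(v) v / sqrt(sum(v^2))

.cross3 <- function(a, b)
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])

## NeRF internal-to-Cartesian placement: new atom bonded to C, with bond
## angle B-C-new and dihedral A-B-C-new (degrees).
.placeAtom <- function(A, B, C, bond, angle, dihedral) {
  angle <- angle * pi / 180
  dihedral <- -dihedral * pi / 180   # sign flip: match .dihedralDeg convention
  bc <- .unitv(C - B)
  n <- .unitv(.cross3(B - A, bc))
  m <- .cross3(n, bc)
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(dihedral),
         bond * sin(angle) * sin(dihedral))
  C + d[1L] * bc + d[2L] * m + d[3L] * n
}

.dihedralDeg <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- .cross3(b1, b2); n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.rot2 <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1L] - sin(th) * v[2L],
    sin(th) * v[1L] + cos(th) * v[2L])
}

## ---- internal: base templates (planar, 3D with z = 0 except methyl H) ----

## Regular hexagon/pentagon ring systems with standard PDB atom names.
## Attachment atom (glycosidic nitrogen) and its outward direction are
## returned so the base can be embedded on the sugar.
.baseTemplate <- function(base) {
  side <- 1.39
  hex <- t(vapply(0:5, function(k) side * c(cos(k * pi / 3),
                                            sin(k * pi / 3)),
                  numeric(2)))
  atoms <- list(); bonds <- list()
  add <- function(name, xy, z = 0)
    atoms[[name]] <<- c(xy[1L], xy[2L], z)
  bond <- function(a, b) bonds[[length(bonds) + 1L]] <<- c(a, b)
  rad <- function(p, centre = c(0, 0)) .unitv(p - centre)

  if (base %in% c("U", "C", "T")) {
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    for (i in seq_len(6L)) add(nm[i], hex[i, ])
    for (i in seq_len(6L)) bond(nm[i], nm[i %% 6L + 1L])
    add("O2", hex[2L, ] + 1.22 * rad(hex[2L, ])); bond("C2", "O2")
    if (base == "C") {
      add("N4", hex[4L, ] + 1.35 * rad(hex[4L, ])); bond("C4", "N4")
      n4 <- atoms[["N4"]][1:2]
      add("H41", n4 + 1.01 * .rot2(rad(hex[4L, ]), 60)); bond("N4", "H41")
      add("H42", n4 + 1.01 * .rot2(rad(hex[4L, ]), -60)); bond("N4", "H42")
      add("H5", hex[5L, ] + 1.08 * rad(hex[5L, ])); bond("C5", "H5")
    } else {
      add("O4", hex[4L, ] + 1.22 * rad(hex[4L, ])); bond("C4", "O4")
      add("H3", hex[3L, ] + 1.01 * rad(hex[3L, ])); bond("N3", "H3")
      if (base == "T") {
        c7 <- hex[5L, ] + 1.50 * rad(hex[5L, ])
        add("C7", c7); bond("C5", "C7")
        add("H71", c7 + 1.09 * rad(hex[5L, ])); bond("C7", "H71")
        add("H72", c7 + 0.36 * rad(hex[5L, ]), 1.03); bond("C7", "H72")
        add("H73", c7 + 0.36 * rad(hex[5L, ]), -1.03); bond("C7", "H73")
      } else {
        add("H5", hex[5L, ] + 1.08 * rad(hex[5L, ])); bond("C5", "H5")
      }
    }
    add("H6", hex[6L, ] + 1.08 * rad(hex[6L, ])); bond("C6", "H6")
    attach <- "N1"
  } else {
    nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
    for (i in seq_len(6L)) add(nm[i], hex[i, ])
    for (i in seq_len(6L)) bond(nm[i], nm[i %% 6L + 1L])
    ## pentagon fused on the C4-C5 edge, on the side away from the
    ## hexagon centre; ring path C4-N9-C8-N7-C5
    P1 <- hex[4L, ]; P2 <- hex[5L, ]
    mid <- (P1 + P2) / 2
    ap <- side / (2 * tan(pi / 5))
    Cp <- mid + ap * .unitv(mid)
    rot <- function(p, deg) Cp + .rot2(p - Cp, deg)
    sgn <- if (sum((rot(P1, 4 * 72) - P2)^2) < 1e-6) 1 else -1
    add("N9", rot(P1, sgn * 72)); add("C8", rot(P1, sgn * 144))
    add("N7", rot(P1, sgn * 216))
    bond("C4", "N9"); bond("N9", "C8"); bond("C8", "N7"); bond("N7", "C5")
    add("H8", atoms[["C8"]][1:2] + 1.08 * rad(atoms[["C8"]][1:2], Cp))
    bond("C8", "H8")
    if (base == "A") {
      add("N6", hex[6L, ] + 1.35 * rad(hex[6L, ])); bond("C6", "N6")
      n6 <- atoms[["N6"]][1:2]
      add("H61", n6 + 1.01 * .rot2(rad(hex[6L, ]), 60)); bond("N6", "H61")
      add("H62", n6 + 1.01 * .rot2(rad(hex[6L, ]), -60)); bond("N6", "H62")
      add("H2", hex[2L, ] + 1.08 * rad(hex[2L, ])); bond("C2", "H2")
    } else {
      add("O6", hex[6L, ] + 1.22 * rad(hex[6L, ])); bond("C6", "O6")
      add("N2", hex[2L, ] + 1.35 * rad(hex[2L, ])); bond("C2", "N2")
      n2 <- atoms[["N2"]][1:2]
      add("H21", n2 + 1.01 * .rot2(rad(hex[2L, ]), 60)); bond("N2", "H21")
      add("H22", n2 + 1.01 * .rot2(rad(hex[2L, ]), -60)); bond("N2", "H22")
      add("H1", hex[1L, ] + 1.01 * rad(hex[1L, ])); bond("N1", "H1")
    }
    attach <- "N9"
  }
  xyz <- do.call(rbind, atoms)
  outward <- if (base %in% c("U", "C", "T")) .unitv(hex[1L, ])
             else .unitv(xyz[attach, 1:2] - Cp)
  list(xyz = xyz, bonds = do.call(rbind, bonds), attach = attach,
       outward = outward)
}

## ---- internal: one nucleotide in a local frame ---------------------------

## Builds sugar + phosphate + base + 2' substituent with standard bond
## parameters (anti chains; stereoelectronic gauche torsions for the
## 2'-MOE OCCO unit and the 2'-MTMM acetal). Returns atoms and the
## declared bond topology.
.buildResidue <- function(base, modification) {
  atoms <- list(); bonds <- list()
  add <- function(name, p) atoms[[name]] <<- p
  bond <- function(a, b) bonds[[length(bonds) + 1L]] <<- c(a, b)
  g <- function(name) atoms[[name]]
  pl <- function(name, A, B, C, bond_, angle, dih, parent = C) {
    add(name, .placeAtom(g(A), g(B), g(C), bond_, angle, dih))
    bond(parent, name)
  }

  ## furanose ring: puckered pentagon, circumradius 1.30
  ringNames <- c("C1'", "C2'", "C3'", "C4'", "O4'")
  puck <- c(0.10, -0.20, 0.20, -0.10, 0.00)
  for (i in seq_len(5L)) {
    th <- (90 - 72 * (i - 1)) * pi / 180
    add(ringNames[i], c(1.30 * cos(th), 1.30 * sin(th), puck[i]))
  }
  for (i in seq_len(5L)) bond(ringNames[i], ringNames[i %% 5L + 1L])

  dih <- function(a, b, c, d) .dihedralDeg(g(a), g(b), g(c), g(d))

  ## C1': glycosidic N and H1' flank the ring O4'
  w1 <- dih("C3'", "C2'", "C1'", "O4'")
  attachName <- if (base %in% c("A", "G")) "N9" else "N1"
  pl(attachName, "C3'", "C2'", "C1'", 1.48, 109.5, w1 + 120,
     parent = "C1'")
  pl("H1'", "C3'", "C2'", "C1'", 1.09, 109.5, w1 - 120, parent = "C1'")

  ## C3': O3' (capped) and H3'
  w3 <- dih("C1'", "C2'", "C3'", "C4'")
  pl("O3'", "C1'", "C2'", "C3'", 1.42, 110, w3 + 120, parent = "C3'")
  pl("H3'", "C1'", "C2'", "C3'", 1.09, 109.5, w3 - 120, parent = "C3'")
  pl("HO3'", "C2'", "C3'", "O3'", 0.96, 108, 180, parent = "O3'")

  ## C4': C5' arm and H4'; then 5'-phosphate
  w4 <- dih("C2'", "C3'", "C4'", "O4'")
  pl("C5'", "C2'", "C3'", "C4'", 1.51, 110, w4 + 120, parent = "C4'")
  pl("H4'", "C2'", "C3'", "C4'", 1.09, 109.5, w4 - 120, parent = "C4'")
  pl("O5'", "C3'", "C4'", "C5'", 1.42, 110, 180, parent = "C5'")
  pl("H5'", "C3'", "C4'", "C5'", 1.09, 109.5, 60, parent = "C5'")
  pl("H5''", "C3'", "C4'", "C5'", 1.09, 109.5, -60, parent = "C5'")
  pl("P", "C4'", "C5'", "O5'", 1.60, 120, 180, parent = "O5'")
  pl("OP1", "C5'", "O5'", "P", 1.48, 110, 60, parent = "P")
  pl("OP2", "C5'", "O5'", "P", 1.48, 110, -60, parent = "P")

  ## C2': the 2' substituent (dihedral slot sub) and H2' (slot hyd)
  w2 <- dih("C4'", "C3'", "C2'", "C1'")
  sub <- w2 + 120; hyd <- w2 - 120
  if (modification == "DNA") {
    pl("H2''", "C4'", "C3'", "C2'", 1.09, 109.5, sub, parent = "C2'")
    pl("H2'", "C4'", "C3'", "C2'", 1.09, 109.5, hyd, parent = "C2'")
  } else if (modification == "FLUORO") {
    pl("F2'", "C4'", "C3'", "C2'", 1.39, 109.5, sub, parent = "C2'")
    pl("H2'", "C4'", "C3'", "C2'", 1.09, 109.5, hyd, parent = "C2'")
  } else if (modification == "RNA") {
    pl("O2'", "C4'", "C3'", "C2'", 1.41, 109.5, sub, parent = "C2'")
    pl("H2'", "C4'", "C3'", "C2'", 1.09, 109.5, hyd, parent = "C2'")
    pl("HO2'", "C3'", "C2'", "O2'", 0.96, 107.5, 180, parent = "O2'")
  } else if (modification == "OME") {
    pl("O2'", "C4'", "C3'", "C2'", 1.41, 109.5, sub, parent = "C2'")
    pl("H2'", "C4'", "C3'", "C2'", 1.09, 109.5, hyd, parent = "C2'")
    pl("CM'", "C3'", "C2'", "O2'", 1.43, 111.5, 180, parent = "O2'")
    pl("HM1", "C2'", "O2'", "CM'", 1.09, 109.5, 180, parent = "CM'")
    pl("HM2", "C2'", "O2'", "CM'", 1.09, 109.5, 60, parent = "CM'")
    pl("HM3", "C2'", "O2'", "CM'", 1.09, 109.5, -60, parent = "CM'")
  } else if (modification == "MOE") {
    pl("O2'", "C4'", "C3'", "C2'", 1.41, 109.5, sub, parent = "C2'")
    pl("H2'", "C4'", "C3'", "C2'", 1.09, 109.5, hyd, parent = "C2'")
    pl("CA'", "C3'", "C2'", "O2'", 1.43, 111.5, 180, parent = "O2'")
    pl("CB'", "C2'", "O2'", "CA'", 1.52, 109.5, 180, parent = "CA'")
    pl("OC'", "O2'", "CA'", "CB'", 1.42, 109.5, 60, parent = "CB'")
    pl("CD'", "CA'", "CB'", "OC'", 1.43, 111.5, 180, parent = "OC'")
    pl("HA1", "C2'", "O2'", "CA'", 1.09, 109.5, 60, parent = "CA'")
    pl("HA2", "C2'", "O2'", "CA'", 1.09, 109.5, -60, parent = "CA'")
    pl("HB1", "O2'", "CA'", "CB'", 1.09, 109.5, -60, parent = "CB'")
    pl("HB2", "O2'", "CA'", "CB'", 1.09, 109.5, 180, parent = "CB'")
    pl("HD1", "CB'", "OC'", "CD'", 1.09, 109.5, 180, parent = "CD'")
    pl("HD2", "CB'", "OC'", "CD'", 1.09, 109.5, 60, parent = "CD'")
    pl("HD3", "CB'", "OC'", "CD'", 1.09, 109.5, -60, parent = "CD'")
  } else if (modification == "FA") {
    pl("N2'", "C4'", "C3'", "C2'", 1.45, 109.5, sub, parent = "C2'")
    pl("H2'", "C4'", "C3'", "C2'", 1.09, 109.5, hyd, parent = "C2'")
    pl("CF'", "C3'", "C2'", "N2'", 1.35, 121, 180, parent = "N2'")
    pl("HN'", "C3'", "C2'", "N2'", 1.01, 118, 0, parent = "N2'")
    pl("OF'", "C2'", "N2'", "CF'", 1.22, 124, 180, parent = "CF'")
    pl("HF'", "C2'", "N2'", "CF'", 1.09, 113, 0, parent = "CF'")
  } else if (modification == "MTMM") {
    pl("O2'", "C4'", "C3'", "C2'", 1.41, 109.5, sub, parent = "C2'")
    pl("H2'", "C4'", "C3'", "C2'", 1.09, 109.5, hyd, parent = "C2'")
    pl("CA'", "C3'", "C2'", "O2'", 1.41, 113, 70, parent = "O2'")
    pl("OB'", "C2'", "O2'", "CA'", 1.41, 111.5, 70, parent = "CA'")
    pl("CC'", "O2'", "CA'", "OB'", 1.41, 113, 180, parent = "OB'")
    pl("SD'", "CA'", "OB'", "CC'", 1.81, 112, 180, parent = "CC'")
    pl("CE'", "OB'", "CC'", "SD'", 1.81, 98.9, 180, parent = "SD'")
    pl("HA1", "C2'", "O2'", "CA'", 1.09, 109.5, 70 + 120, parent = "CA'")
    pl("HA2", "C2'", "O2'", "CA'", 1.09, 109.5, 70 - 120, parent = "CA'")
    pl("HC1", "CA'", "OB'", "CC'", 1.09, 109.5, 60, parent = "CC'")
    pl("HC2", "CA'", "OB'", "CC'", 1.09, 109.5, -60, parent = "CC'")
    pl("HE1", "CC'", "SD'", "CE'", 1.09, 109.5, 180, parent = "CE'")
    pl("HE2", "CC'", "SD'", "CE'", 1.09, 109.5, 60, parent = "CE'")
    pl("HE3", "CC'", "SD'", "CE'", 1.09, 109.5, -60, parent = "CE'")
  } else stop("unknown modification code: ", modification)

  ## embed the base template in the plane anchored at the glycosidic N
  tpl <- .baseTemplate(base)
  Npos <- g(attachName)
  d1 <- .unitv(g("C1'") - Npos)
  ref <- .unitv(g("C2'") - g("C1'"))
  ## base normal in the sugar plane so the base extends perpendicular to
  ## the sugar rather than slicing through it
  d3 <- .unitv(ref - sum(ref * d1) * d1)
  d2 <- .cross3(d3, d1)
  e1 <- c(tpl$outward, 0)
  e2 <- c(-tpl$outward[2L], tpl$outward[1L], 0)
  e3 <- c(0, 0, 1)
  origin <- tpl$xyz[tpl$attach, ]
  for (nm in rownames(tpl$xyz)) {
    if (nm == tpl$attach) next
    q <- tpl$xyz[nm, ] - origin
    qq <- c(sum(q * e1), sum(q * e2), sum(q * e3))
    add(nm, Npos + qq[1L] * d1 + qq[2L] * d2 + qq[3L] * d3)
  }
  for (i in seq_len(nrow(tpl$bonds)))
    bond(tpl$bonds[i, 1L], tpl$bonds[i, 2L])

  xyz <- do.call(rbind, atoms)
  b <- do.call(rbind, bonds)
  swap <- b[, 1L] > b[, 2L]
  b[swap, ] <- b[swap, c(2L, 1L)]
  b <- b[!duplicated(paste(b[, 1L], b[, 2L])), , drop = FALSE]
  b <- b[order(b[, 1L], b[, 2L]), , drop = FALSE]
  list(names = rownames(xyz), xyz = unname(xyz),
       bonds = data.frame(atom1 = b[, 1L], atom2 = b[, 2L],
                          stringsAsFactors = FALSE))
}

#' Declared topology of a template nucleotide
#'
#' The bond list the residue builder lays down -- the manifest that
#' covalent-bond inference is validated against.
#'
#' @param base base code (A/U/G/C/T).
#' @param modification modification code.
#' @return data.frame with columns `atom1`, `atom2` (each bond once,
#'   lexicographic order).
#' @export
residueTopology <- function(base, modification = "RNA")
  .buildResidue(base, modification)$bonds

#' Generate an idealized helical guide-RNA structure
#'
#' Places full nucleotides (standard atom names, complete nucleobase
#' heavy-atom sets, sugar, 5'-phosphate, and the 2' substituent dictated
#' by each position's modification code) on an idealized helix. The
#' default rise and twist are A-form-like; the geometry is an idealized
#' synthetic stand-in, adequate because distortion scoring depends only
#' on displacement fields between models built in the same frame.
#' Deterministic: the same arguments always give identical coordinates.
#'
#' @param sequence guide sequence, 5' to 3', alphabet A/U/G/C/T,
#'   length >= 1 (>= 9 nt for full seed-window scoring).
#' @param modifications named character vector position -> modification
#'   code; unlisted positions are unmodified RNA.
#' @param rise helical rise per residue, Angstroms.
#' @param twist helical twist per residue, degrees.
#' @param modelId model identifier.
#' @return a [GuideStructure-class] with source `"SYNTHETIC"`.
#' @examples
#' makeGuideStructure("UUUUUUUUU")
#' @export
makeGuideStructure <- function(sequence, modifications = NULL,
                               rise = 2.8, twist = 32.7,
                               modelId = "synthetic_guide") {
  bases <- strsplit(toupper(sequence), "")[[1L]]
  if (!length(bases) || !all(bases %in% .BASES))
    stop("invalid base(s) in sequence: ",
         paste(unique(setdiff(bases, .BASES)), collapse = ", "))
  mods <- rep("RNA", length(bases))
  if (!is.null(modifications)) {
    idx <- as.integer(names(modifications))
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(bases)))
      stop("modification positions must index into the sequence")
    mods[idx] <- toupper(unname(modifications))
  }
  if (!all(mods %in% .MODIFICATIONS))
    stop("unrecognised modification code(s): ",
         paste(setdiff(mods, .MODIFICATIONS), collapse = ", "))
  rows <- list()
  for (k in seq_along(bases)) {
    res <- .buildResidue(bases[k], mods[k])
    th <- (k - 1L) * twist * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                3L, 3L)
    xyz <- sweep(res$xyz, 2L, c(9.4, 0, 0), `+`) %*% t(R)
    xyz[, 3L] <- xyz[, 3L] + (k - 1L) * rise
    rows[[k]] <- data.frame(
      serial = 0L, atom = res$names,
      element = .elementFromName(res$names),
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      occupancy = 1, altLoc = "",
      guidePosition = k, base = bases[k], modification = mods[k],
      stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  .newGuideStructure(modelId, at, "SYNTHETIC")
}

#' Perturb nucleobase atoms with a known displacement field
#'
#' Applies either an isotropic Gaussian displacement (sd per coordinate)
#' or a fixed rigid shift to the nucleobase heavy atoms of the given
#' positions, and returns the analytically expected distortion values
#' computed from the realized (not nominal) displacements -- the ground
#' truth for recovery tests.
#'
#' @param model a [GuideStructure-class].
#' @param positions guide positions whose nucleobase heavy atoms are
#'   displaced.
#' @param sd per-coordinate Gaussian displacement, Angstroms.
#' @param shift optional numeric(3); when given, a rigid shift is applied
#'   instead of Gaussian noise.
#' @param seed RNG seed for the Gaussian case.
#' @return list with `model` (the perturbed [GuideStructure-class]),
#'   `displacements` (data.frame of per-atom displacement magnitudes) and
#'   `expected` (list: `perNucleotide` named vector, and the window
#'   values `POOLED`, `SUM_RMSD`, `SUM_MSD` over exactly `positions`).
#' @export
perturbStructure <- function(model, positions, sd = 0.3, shift = NULL,
                             seed = NULL) {
  at <- atomTable(model)
  disp <- list()
  for (p in positions) {
    hv <- nucleobaseHeavyAtoms(model, p)
    idx <- match(paste(p, hv$atom), paste(at$guidePosition, at$atom))
    d <- if (!is.null(shift)) {
      matrix(rep(shift, each = length(idx)), ncol = 3L)
    } else {
      .withSeed(if (is.null(seed)) NULL else seed + p,
                matrix(stats::rnorm(3L * length(idx), sd = sd),
                       ncol = 3L))
    }
    at$x[idx] <- at$x[idx] + d[, 1L]
    at$y[idx] <- at$y[idx] + d[, 2L]
    at$z[idx] <- at$z[idx] + d[, 3L]
    disp[[as.character(p)]] <- data.frame(
      guidePosition = p, atom = hv$atom,
      delta = sqrt(rowSums(d^2)), stringsAsFactors = FALSE)
  }
  disp <- do.call(rbind, disp)
  perNuc <- vapply(split(disp$delta, disp$guidePosition),
                   function(d) sqrt(mean(d^2)), numeric(1))
  Kj <- vapply(split(disp$delta, disp$guidePosition), length, integer(1))
  expected <- list(
    perNucleotide = perNuc,
    POOLED = sqrt(sum(Kj * perNuc^2) / sum(Kj)),
    SUM_RMSD = sum(perNuc),
    SUM_MSD = sum(perNuc^2))
  out <- .newGuideStructure(paste0(modelId(model), "_perturbed"), at,
                            "SYNTHETIC")
  list(model = out, displacements = disp, expected = expected)
}

## ---- assay-side generators -----------------------------------------------

#' Simulate dual-luciferase reporter measurements
#'
#' Draws replicate Renilla/firefly luminescence pairs with multiplicative
#' (log-normal) noise around the declared true relative activities, and
#' appends matching control-siRNA rows (true activity 100%) for every
#' (reporter, concentration) stratum.
#'
#' @param trueActivities data.frame with columns `sirna_id`, `reporter`
#'   (`"CM"` or `"SM"`), `concentration` (nM) and `activity`
#'   (true relative activity, % of control).
#' @param cv coefficient of variation of the multiplicative noise.
#' @param reps replicates per condition.
#' @param seed RNG seed.
#' @param baseRenilla,baseFirefly control-level mean luminescence.
#' @return data.frame of reporter measurements (`sirna_id`, `reporter`,
#'   `concentration`, `replicate`, `renilla`, `firefly`).
#' @export
simulateReporter <- function(trueActivities, cv = 0.1, reps = 3L,
                             seed = NULL, baseRenilla = 1e5,
                             baseFirefly = 2e5) {
  need <- c("sirna_id", "reporter", "concentration", "activity")
  if (!all(need %in% names(trueActivities)))
    stop("trueActivities is missing column(s): ",
         paste(setdiff(need, names(trueActivities)), collapse = ", "))
  if (cv < 0 || reps < 1L) stop("invalid cv or reps")
  strata <- unique(trueActivities[, c("reporter", "concentration")])
  ctl <- data.frame(sirna_id = "siCont", reporter = strata$reporter,
                    concentration = strata$concentration, activity = 100)
  cond <- rbind(trueActivities[, need], ctl)
  sdlog <- sqrt(log(1 + cv^2))
  .withSeed(seed, {
    n <- nrow(cond) * reps
    out <- cond[rep(seq_len(nrow(cond)), each = reps), ]
    out$replicate <- rep(seq_len(reps), nrow(cond))
    out$renilla <- baseRenilla * out$activity / 100 *
      stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    out$firefly <- baseFirefly * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    out$activity <- NULL
    rownames(out) <- NULL
    out
  })
}

#' Simulate a two-state melting curve
#'
#' Absorbance at 260 nm modelled as sloped baselines joined by a logistic
#' transition centred at the true Tm, plus Gaussian noise.
#'
#' @param tm true melting temperature, degrees Celsius.
#' @param width logistic width parameter, degrees Celsius.
#' @param lower,upper folded/unfolded baseline absorbance at the start
#'   temperature.
#' @param slope common baseline slope, AU per degree.
#' @param noiseSd Gaussian noise sd, AU.
#' @param from,to,spacing temperature program, degrees Celsius.
#' @param seed RNG seed.
#' @return list with `curve` (data.frame `temperature_C`, `a260`) and the
#'   generating parameters (`tm`, `width`, ...).
#' @export
simulateMelting <- function(tm = 74.5, width = 2.5, lower = 0.90,
                            upper = 1.08, slope = 3e-4, noiseSd = 0.002,
                            from = 30, to = 90, spacing = 0.5,
                            seed = NULL) {
  if (width <= 0 || spacing <= 0 || to <= from || noiseSd < 0)
    stop("invalid melting-curve parameters")
  temp <- seq(from, to, by = spacing)
  a <- lower + slope * (temp - from) +
    (upper - lower) / (1 + exp(-(temp - tm) / width))
  a <- .withSeed(seed, a + stats::rnorm(length(a), sd = noiseSd))
  list(curve = data.frame(temperature_C = temp, a260 = a),
       tm = tm, width = width, lower = lower, upper = upper,
       slope = slope, noiseSd = noiseSd, spacing = spacing)
}

#' Simulate an expression matrix with a planted seed-match down-shift
#'
#' Generates mock and treated intensity columns with log-normal
#' transcript abundances and per-sample log2 noise; a declared fraction
#' of transcripts is seed-matched (SM) and receives an additional log2
#' fold-change effect in the treated sample. When UTRs are generated,
#' the seed-complementary 7-mer is planted in every SM transcript's
#' 3'UTR and scrubbed from every non-SM UTR, so sequence-based
#' classification recovers the truth exactly.
#'
#' @param nTranscripts number of transcripts.
#' @param smFraction fraction of seed-matched transcripts.
#' @param effectL2fc planted SM log2 fold-change effect (treated only).
#' @param noiseSd per-sample log2 noise sd.
#' @param utrLength 3'UTR length, nt.
#' @param guide guide-strand sequence the seed is taken from.
#' @param baseMean,baseSd log2 abundance distribution.
#' @param makeUtrs set FALSE to skip sequence generation (expression-only
#'   simulations).
#' @param seed RNG seed.
#' @return list with `matrix` (transcripts x c(mock, treated), RefSeq-like
#'   rownames), `smTruth` (logical), `utr3` (named character vector or
#'   NULL), `flags` (all-passing QC-flag data.frame), `seed7`
#'   (the guide seed), and the generating parameters.
#' @export
simulateExpression <- function(nTranscripts = 2000L, smFraction = 0.1,
                               effectL2fc = -1, noiseSd = 0.25,
                               utrLength = 300L,
                               guide = "UACGGAUCAAUCGGUACUGAU",
                               baseMean = 8, baseSd = 1.5,
                               makeUtrs = TRUE, seed = NULL) {
  if (nTranscripts < 2L || smFraction <= 0 || smFraction >= 1 ||
      noiseSd < 0 || utrLength < 7L)
    stop("invalid expression-simulation parameters")
  seed7 <- seedOf(guide)
  target <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", seed7))))
  .withSeed(seed, {
    nSM <- max(1L, round(nTranscripts * smFraction))
    sm <- c(rep(TRUE, nSM), rep(FALSE, nTranscripts - nSM))
    ids <- sprintf("NM_%06d", seq_len(nTranscripts))
    base <- stats::rnorm(nTranscripts, baseMean, baseSd)
    mock <- 2^(base + stats::rnorm(nTranscripts, sd = noiseSd))
    treat <- 2^(base + stats::rnorm(nTranscripts, sd = noiseSd) +
                ifelse(sm, effectL2fc, 0))
    mat <- cbind(mock = mock, treated = treat)
    rownames(mat) <- ids
    utr3 <- NULL
    if (makeUtrs) {
      letters4 <- c("A", "C", "G", "T")
      utr3 <- vapply(seq_len(nTranscripts), function(i)
        paste(sample(letters4, utrLength, replace = TRUE),
              collapse = ""), character(1))
      ## scrub chance occurrences everywhere, then plant in SM UTRs
      for (i in seq_len(nTranscripts)) {
        while (grepl(target, utr3[i], fixed = TRUE)) {
          at <- regexpr(target, utr3[i], fixed = TRUE)
          flip <- setdiff(letters4, substr(utr3[i], at, at))
          substr(utr3[i], at, at) <- sample(flip, 1L)
        }
      }
      for (i in which(sm)) {
        pos <- sample.int(utrLength - 6L, 1L)
        substr(utr3[i], pos, pos + 6L) <- target
      }
      names(utr3) <- ids
    }
    flags <- data.frame(transcript_id = ids, ControlType = 0L,
                        gIsPosAndSignif = 1L, gIsFeatNonUnifOL = 0L,
                        gIsWellAboveBG = 1L, gIsSaturated = 0L,
                        gIsFeatPopnOL = 0L, stringsAsFactors = FALSE)
    list(matrix = mat, smTruth = sm, utr3 = utr3, flags = flags,
         seed7 = seed7, guide = guide,
         params = list(nTranscripts = nTranscripts,
                       smFraction = smFraction, effectL2fc = effectL2fc,
                       noiseSd = noiseSd))
  })
}
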