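test_that("a minimal well-formed ATOM record parses into one atom", {
  m <- readPDB(pdbLine(x = 12.345, y = -6.789, z = 0.120))
  at <- atomTable(m)
  expect_equal(nrow(at), 1L)
  expect_equal(at$atom, "N1")
  expect_equal(at$guidePosition, 2L)
  expect_equal(c(at$x, at$y, at$z), c(12.345, -6.789, 0.120))
  expect_equal(at$base, "A")
})

test_that("alt-loc duplicates resolve to the highest-occupancy copy", {
  lines <- c(pdbLine(1, altLoc = "A", x = 1, occ = 0.6),
             pdbLine(2, altLoc = "B", x = 2, occ = 0.4))
  at <- atomTable(readPDB(lines))
  expect_equal(nrow(at), 1L)
  expect_equal(at$x, 1.0)
  expect_equal(at$altLoc, "A")
  ## occupancy tie resolves to the lexicographically smallest code
  tied <- c(pdbLine(1, altLoc = "B", x = 1, occ = 0.5),
            pdbLine(2, altLoc = "A", x = 2, occ = 0.5))
  expect_equal(atomTable(readPDB(tied))$altLoc, "A")
})

test_that("malformed records and insertion codes are rejected with context", {
  bad <- sub("12.345", "xx.xxx", pdbLine(x = 12.345), fixed = TRUE)
  expect_error(readPDB(bad), "line 1")
  expect_error(readPDB(pdbLine(iCode = "A")), "insertion")
})

test_that("generated structures round-trip through PDB", {
  m <- makeGuideStructure("UAC", modifications = c("2" = "MOE"))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(m, f)
  back <- readPDB(f, modifications = c("2" = "MOE"))
  a0 <- atomTable(m); a1 <- atomTable(back)
  expect_equal(nrow(a1), nrow(a0))
  expect_setequal(paste(a1$guidePosition, a1$atom),
                  paste(a0$guidePosition, a0$atom))
  i <- match(paste(a0$guidePosition, a0$atom),
             paste(a1$guidePosition, a1$atom))
  expect_equal(a1$x[i], a0$x, tolerance = 1e-3)
  expect_equal(a1$z[i], a0$z, tolerance = 1e-3)
  expect_equal(a1$base[i], a0$base)
})

test_that("PDB parsing agrees with an independent reader", {
  m <- makeGuideStructure("GAU")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(m, f)
  ref <- bio3d::read.pdb(f)
  mine <- atomTable(readPDB(f))
  expect_equal(nrow(mine), nrow(ref$atom))
  i <- order(ref$atom$eleno)
  expect_equal(mine$x, ref$atom$x[i], tolerance = 1e-9)
  expect_equal(mine$y, ref$atom$y[i], tolerance = 1e-9)
  expect_equal(mine$guidePosition, ref$atom$resno[i])
})

test_that("annotated XYZ reading reproduces the PDB rendering", {
  m <- makeGuideStructure("UAC", modifications = c("3" = "FA"))
  cf <- withr::local_tempfile(fileext = ".xyz")
  mf <- withr::local_tempfile(fileext = ".tsv")
  writeStructureXYZ(m, cf, mf)
  back <- readAnnotatedXYZ(cf, mf)
  a0 <- atomTable(m); a1 <- atomTable(back)
  i <- match(paste(a0$guidePosition, a0$atom),
             paste(a1$guidePosition, a1$atom))
  expect_false(anyNA(i))
  expect_equal(a1$x[i], a0$x, tolerance = 1e-5)
  expect_equal(a1$modification[i], a0$modification)
  expect_equal(structureSource(back), "XYZ_ANNOTATED")
})

test_that("annotated XYZ contract violations are reported by row", {
  coords <- data.frame(element = c("N", "C", "O"),
                       x = 0:2, y = 0, z = 0)
  map <- data.frame(guide_position = 1L, base = "U",
                    modification = "RNA",
                    atom_name = c("N1", "C2", "O2"))
  m <- readAnnotatedXYZ(coords, map)
  expect_equal(nrow(atomTable(m)), 3L)
  expect_equal(length(guidePositions(m)), 1L)
  expect_error(readAnnotatedXYZ(coords[1:2, ], map), "mismatch")
  badmap <- map; badmap$atom_name[1L] <- "C1'"
  expect_error(readAnnotatedXYZ(coords, badmap), "row 1")
})

test_that("nucleobase heavy-atom sets follow standard nomenclature", {
  counts <- c(A = 10L, G = 11L, C = 8L, U = 8L, T = 9L)
  for (b in names(counts)) {
    s <- makeGuideStructure(paste(rep(b, 3), collapse = ""))
    hv <- nucleobaseHeavyAtoms(s, 2)
    expect_equal(nrow(hv), counts[[b]], info = b)
    expect_false(any(hv$element %in% c("H", "D")), info = b)
    expect_false(any(grepl("'", hv$atom)), info = b)  # no sugar atoms
  }
  a <- nucleobaseHeavyAtoms(makeGuideStructure("AAA"), 1)
  expect_setequal(a$atom, c("N1", "C2", "N3", "C4", "C5", "C6",
                            "N6", "N7", "C8", "N9"))
  u <- nucleobaseHeavyAtoms(makeGuideStructure("UUU"), 1)
  expect_setequal(u$atom, c("N1", "C2", "O2", "N3", "C4", "O4",
                            "C5", "C6"))
})

test_that("incomplete residues are reported with the missing atom names", {
  s <- makeGuideStructure("UUU")
  at <- atomTable(s)
  crippled <- toyStructure(
    at[!(at$guidePosition == 2 & at$atom %in% c("O4", "C5")),
       c("atom", "element", "x", "y", "z", "guidePosition", "base")])
  err <- tryCatch(nucleobaseHeavyAtoms(crippled, 2),
                  error = conditionMessage)
  expect_match(err, "O4")
  expect_match(err, "C5")
})

test_that("atom pairing measures frame distances without superposition", {
  m <- makeGuideStructure("UACGG")
  expect_equal(max(pairTable(pairByName(m, m))$delta), 0)
  shifted <- translateStructure(m, c(0.3, 0, 0.4))
  expect_equal(unique(round(pairTable(pairByName(shifted, m))$delta, 12)),
               0.5)
  ## pairing is symmetric in its arguments
  p1 <- pairTable(pairByName(shifted, m))
  p2 <- pairTable(pairByName(m, shifted))
  expect_equal(p1$delta, p2$delta)
  ## translating BOTH models leaves every delta unchanged
  p3 <- pairTable(pairByName(translateStructure(shifted, c(5, -2, 1)),
                             translateStructure(m, c(5, -2, 1))))
  expect_equal(p3$delta, p1$delta)
})

test_that("pairing deltas match a brute-force double loop", {
  pair <- randomToyPair(5, seed = 42)
  sel <- list("1" = paste0("X", 1:5))
  p <- pairTable(pairByName(pair$a, pair$b, sel))
  ta <- atomTable(pair$a); tb <- atomTable(pair$b)
  for (k in seq_len(5)) {
    d <- NA
    for (i in seq_len(nrow(ta))) for (j in seq_len(nrow(tb)))
      if (ta$atom[i] == p$atom[k] && tb$atom[j] == p$atom[k])
        d <- sqrt((ta$x[i] - tb$x[j])^2 + (ta$y[i] - tb$y[j])^2 +
                  (ta$z[i] - tb$z[j])^2)
    expect_equal(p$delta[k], d, tolerance = 1e-12)
  }
})

test_that("pairing reports all orphans when atoms are missing", {
  m <- makeGuideStructure("UU")
  sel <- list("1" = c("N1", "NOPE1", "NOPE2"))
  err <- tryCatch(pairByName(m, m, sel), error = conditionMessage)
  expect_match(err, "NOPE1")
  expect_match(err, "NOPE2")
})

test_that("Kabsch mode removes a rigid offset", {
  m <- makeGuideStructure("UACG")
  shifted <- translateStructure(m, c(1, 2, 3))
  p <- pairByName(shifted, m, superpose = TRUE)
  expect_lt(max(pairTable(p)$delta), 1e-9)
})
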