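test_that("PDB loading round-trips fixture structures and reports errors", {
  hp <- makeToyHairpin(nBeads = 16)
  s <- loadStructure(hp$pdbText)
  expect_equal(nBeads(s), 16L)
  expect_identical(beadCoords(s), beadCoords(hp$structure))

  # 4-residue toy written and re-read exactly
  sq <- beadStructure(cbind(c(0, 5, 5, 0), c(0, 0, 5, 5), c(0, 0, 0, 0)))
  rt <- loadStructure(writeStructurePDB(sq, chain = "B"), chain = "B")
  expect_identical(beadCoords(rt), beadCoords(sq))

  expect_error(loadStructure(hp$pdbText, chain = "Z"), "available chains.*A")

  # a residue with atoms but no C-alpha is a gap
  lines <- writeStructurePDB(sq)
  lines[2] <- sub(" CA ", " CB ", lines[2], fixed = TRUE)
  expect_error(loadStructure(lines), "gap.*2")
})

test_that("altloc resolution picks highest occupancy then label", {
  sq <- beadStructure(cbind(c(0, 5, 5, 0), c(0, 0, 5, 5), c(0, 0, 0, 0)))
  lines <- writeStructurePDB(sq)
  # give residue 1 two altlocs with different occupancies and positions
  a <- "ATOM     91  CA AGLY A   1       9.000   0.000   0.000  0.40  0.00           C"
  b <- "ATOM     92  CA BGLY A   1       0.000   0.000   0.000  0.60  0.00           C"
  s <- loadStructure(c(a, b, lines[2:4], "END"))
  expect_equal(beadCoords(s)[1, 1], 0)  # the 0.60-occupancy B altloc
})

test_that("native contact detection applies both distance and separation filters", {
  # collinear beads 3.8 A apart: every close pair fails the separation
  # filter, the (1,4) pair passes it but exceeds the cutoff
  collinear <- beadStructure(cbind(0, c(0, 3.8, 7.6, 11.4), 0))
  cm0 <- computeNativeContacts(collinear, cutoff = 8, minSeparation = 3)
  expect_equal(nrow(contactPairs(cm0)), 0L)

  sq <- beadStructure(cbind(c(0, 5, 5, 0), c(0, 0, 5, 5), c(0, 0, 0, 0)))
  cm <- computeNativeContacts(sq, cutoff = 8, minSeparation = 3)
  expect_equal(contactPairs(cm)[, c("i", "j")],
               data.frame(i = 1L, j = 4L))
  expect_equal(contactPairs(cm)$r0, 5)

  cm4 <- computeNativeContacts(sq, cutoff = 4, minSeparation = 3)
  expect_equal(nrow(contactPairs(cm4)), 0L)
})

test_that("AFF assembly reproduces construct arithmetic and frame remapping", {
  # miniature construct: every N'-only contact touches the duplicated copy
  toy <- makeToyAFF(eps = 1)  # explicit eps skips calibration
  topo <- topology(toy$model)
  expect_equal(topo@totalLength, 32L)
  cp <- contactPairs(contacts(toy$model))
  np <- cp[cp$frame_tag == "Nprime", ]
  expect_true(all(pmin(np$i, np$j) <= 12))

  # remapping closure: N' contacts map back onto the parent contact set
  wt <- contactPairs(toy$parentContacts)
  wtKey <- sort(paste(wt$i, wt$j))
  offset <- 12L
  backMap <- function(cidx) ifelse(cidx <= 10L, cidx + 10L, cidx - offset)
  npBack <- data.frame(i = backMap(np$i), j = backMap(np$j))
  npKey <- paste(pmin(npBack$i, npBack$j), pmax(npBack$i, npBack$j))
  expect_true(all(npKey %in% wtKey))
  # N-frame contacts are the parent contacts shifted by the offset
  nOnly <- cp[cp$frame_tag %in% c("N", "shared"), ]
  expect_setequal(paste(nOnly$i - offset, nOnly$j - offset), wtKey)
  # multiset of (r0, eps) identical across the two frames before mutation
  nn <- cp[cp$frame_tag == "N", ]
  expect_equal(sort(np$r0), sort(nn$r0), tolerance = 1e-12)
  expect_equal(sort(np$eps), sort(nn$eps), tolerance = 1e-12)

  # single counting
  expect_equal(sum(cp$frame_tag == "N") + sum(cp$frame_tag == "Nprime") +
                 sum(cp$frame_tag == "shared"), nrow(cp))
  expect_equal(anyDuplicated(paste(cp$i, cp$j)), 0L)
})

test_that("degenerate construct (no duplication, no linker) is the parent", {
  hp <- makeToyHairpin(nBeads = 16)
  m <- buildAFFModel(hp$structure, hp$contacts, dupRange = NULL,
                     linkerLength = 0L)
  expect_equal(topology(m)@totalLength, 16L)
  expect_equal(length(topology(m)@frameNprime), 0L)
  cp <- contactPairs(contacts(m))
  expect_equal(nrow(cp), nrow(contactPairs(hp$contacts)))
  expect_true(all(cp$frame_tag == "N"))
})

test_that("construct-length arithmetic holds across fixture constructs", {
  hp <- makeToyHairpin(nBeads = 20)
  cases <- list(c(11, 20, 2), c(15, 20, 6), c(11, 20, 0))
  for (cs in cases) {
    m <- buildAFFModel(hp$structure, hp$contacts,
                       dupRange = cs[1:2], linkerLength = cs[3])
    topo <- topology(m)
    expect_equal(topo@totalLength,
                 20L + (cs[2] - cs[1] + 1L) + cs[3])
    expect_setequal(intersect(topo@frameN, topo@frameNprime), topo@shared)
  }
})

test_that("delete-attractive mutation removes exactly the residue's wells", {
  toy <- makeToyAFF(eps = 1.2)
  m <- toy$model
  res <- toy$candidateResidue
  cp <- contactPairs(contacts(m))
  deleted <- sum(cp$eps[cp$i == res | cp$j == res])
  expect_gt(deleted, 0)
  mut <- applyMutation(m, mutationSpec(res, "cand"))
  # at a geometry where the residue's wells sit at their minima, the full
  # potential rises by exactly the summed deleted well depths (the
  # repulsive cores vanish at r0); in the N reference the residue's
  # N-frame wells are at r0 and its N'-frame partners far beyond range
  cpRes <- cp[(cp$i == res | cp$j == res), ]
  atMin <- abs(sqrt(rowSums((m@refN[cpRes$i, , drop = FALSE] -
                               m@refN[cpRes$j, , drop = FALSE])^2)) -
                 cpRes$r0) < 1e-6
  expectRise <- sum(cpRes$eps[atMin]) -
    sum(vapply(which(!atMin), function(q) {
      r <- sqrt(sum((m@refN[cpRes$i[q], ] - m@refN[cpRes$j[q], ])^2))
      s <- cpRes$r0[q] / r
      cpRes$eps[q] * (5 * s^12 - 6 * s^10)
    }, numeric(1)))
  dE <- potentialEnergy(mut, m@refN) - potentialEnergy(m, m@refN)
  expect_equal(dE, expectRise, tolerance = 1e-8)
  # bonded terms untouched, input unmodified, idempotent
  expect_identical(mut@bonds, m@bonds)
  expect_equal(sum(contactPairs(contacts(m))$eps), sum(cp$eps))
  mut2 <- applyMutation(mut, mutationSpec(res, "cand"))
  expect_identical(contactPairs(contacts(mut2)),
                   contactPairs(contacts(mut)))
  expect_error(applyMutation(m, mutationSpec(999L)), "unknown residue")
})

test_that("mutation never decreases the energy of any configuration", {
  toy <- makeToyAFF(eps = 1.2)
  m <- toy$model
  mut <- applyMutation(m, mutationSpec(toy$candidateResidue))
  set.seed(42)
  for (k in 1:10) {
    X <- m@refN + matrix(rnorm(length(m@refN), sd = runif(1, 0.05, 1)),
                         ncol = 3)
    expect_gte(potentialEnergy(mut, X) - potentialEnergy(m, X), -1e-9)
  }
})

test_that("ligand bias scales only the stated frame's wells", {
  toy <- makeToyAFF(eps = 1)
  m <- toy$model
  # identity at scale 1
  b1 <- applyLigandBias(m, ligandBias("Nprime", 1))
  expect_identical(contactPairs(contacts(b1)), contactPairs(contacts(m)))
  # scaling raises N' well depths only
  b <- applyLigandBias(m, ligandBias("Nprime", 1.2))
  cp0 <- contactPairs(contacts(m)); cp <- contactPairs(contacts(b))
  expect_equal(cp$eps[cp$frame_tag == "Nprime"],
               1.2 * cp0$eps[cp0$frame_tag == "Nprime"])
  expect_equal(cp$eps[cp$frame_tag != "Nprime"],
               cp0$eps[cp0$frame_tag != "Nprime"])
  # a pair belonging to the N frame is rejected
  nPair <- cp0[cp0$frame_tag == "N", c("i", "j")][1, ]
  expect_error(
    applyLigandBias(m, ligandBias("Nprime", 1.2,
                                  pairs = as.matrix(nPair))),
    "outside the stated frame")
})

test_that("contact map TSV export round-trips", {
  hp <- makeToyHairpin(nBeads = 16)
  f <- tempfile(fileext = ".tsv")
  writeContactMap(hp$contacts, f)
  back <- utils::read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$i, contactPairs(hp$contacts)$i)
  expect_equal(back$r0, contactPairs(hp$contacts)$r0, tolerance = 1e-12)
})
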