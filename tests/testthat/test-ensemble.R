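test_that("free-energy fields follow -kT ln P and pool archives correctly", {
  sA <- stateDefinition("A", -Inf, 1)
  sB <- stateDefinition("B", 4, Inf)
  mk <- function(ps, xs) {
    its <- replicate(20, list(weight = ps, pcoord = matrix(xs, ncol = 1),
                              label = rep(NA_character_, length(ps)),
                              parent = rep(0L, length(ps)),
                              parentRecycled = rep(FALSE, length(ps)),
                              recycled = rep(FALSE, length(ps)),
                              binCount = 1L),
                     simplify = FALSE)
    syntheticArchive(its, mode = "equilibrium", flux = rep(0, 20),
                     initial = sA, target = sB)
  }
  kT <- R_KCAL * 293.15
  # uniform weights over 4 cells: G constant
  arcU <- mk(rep(0.25, 4), c(0.5, 1.5, 2.5, 3.5))
  fU <- freeEnergySurface(arcU, breaks = list(0:4), kT = kT)
  expect_equal(max(fU@G) - min(fU@G), 0, tolerance = 1e-12)
  expect_equal(sum(fU@P), 1, tolerance = 1e-12)

  # two cells at 0.9/0.1: dG = kT ln 9 = 1.280 kcal/mol at 293.15 K
  arc2 <- mk(c(0.9, 0.1), c(0.5, 1.5))
  f2 <- freeEnergySurface(arc2, breaks = list(0:2), kT = kT)
  expect_equal(f2@G[2] - f2@G[1], kT * log(9), tolerance = 1e-12)
  expect_equal(f2@G[2] - f2@G[1], 1.280, tolerance = 1e-3)

  # argmax P is argmin G (class invariant, checked on construction)
  expect_equal(which.max(f2@P), which.min(f2@G))

  # pooling two archives averages their normalized fields
  fPool <- freeEnergySurface(list(arc2, arc2), breaks = list(0:2), kT = kT)
  expect_equal(fPool@P, f2@P, tolerance = 1e-12)
})

test_that("transition paths start after the last exit and end at first entry", {
  sI <- stateDefinition("i", -Inf, 1)
  sJ <- stateDefinition("j", 9, Inf)
  # scripted label sequence i, i, b, b, j -> path = frames 3..5
  arc <- scriptedArchive(c(0.5, 0.8, 3, 4, 9.5), recycledAt = 5L,
                         initial = sI, target = sJ)
  paths <- extractTPE(arc, sI, sJ, burnIn = 0)
  expect_length(paths, 1L)
  expect_equal(paths[[1]]$iterations, 3:5)
  expect_equal(as.numeric(paths[[1]]$pcoords), c(3, 4, 9.5))
  expect_equal(paths[[1]]$weight, 1)
  expect_equal(paths[[1]]$duration, 3)

  # i, b, i, b, j -> path starts after the second i visit
  arc2 <- scriptedArchive(c(0.5, 3, 0.7, 4, 9.5), recycledAt = 5L,
                          initial = sI, target = sJ)
  expect_equal(extractTPE(arc2, sI, sJ, burnIn = 0)[[1]]$iterations, 4:5)

  # i, b, i: never reaches j -> no path
  arc3 <- scriptedArchive(c(0.5, 3, 0.7), recycledAt = integer(0),
                          initial = sI, target = sJ)
  expect_length(extractTPE(arc3, sI, sJ, burnIn = 0), 0L)

  # no intermediate frame lies inside either state
  set.seed(3)
  for (k in 1:5) {
    xs <- c(0.5, runif(6, 1.5, 8.5), 9.5)
    arcR <- scriptedArchive(xs, recycledAt = length(xs),
                            initial = sI, target = sJ)
    p <- extractTPE(arcR, sI, sJ, burnIn = 0)[[1]]
    interior <- p$pcoords[-nrow(p$pcoords), , drop = FALSE]
    expect_false(any(inState(interior, sI) | inState(interior, sJ)))
  }
})

test_that("TPE path weight is bounded by the recycled flux", {
  dw <- makeDoubleWell(barrier = 3)
  cfg <- weConfig("steady-state", binEdges = dw$binEdges,
                  walkersPerBin = 4, nIterations = 150,
                  initial = dw$stateA, target = dw$stateB, seed = 21,
                  burnIn = 0)
  arc <- runWE(dw$propagator, cfg)
  paths <- extractTPE(arc, burnIn = 0)
  expect_gt(length(paths), 0L)
  totalPathWeight <- sum(vapply(paths, `[[`, numeric(1), "weight"))
  expect_lte(totalPathWeight, sum(recycledFlux(arc)) + 1e-12)
})

test_that("contact scores reproduce hand-computed ensemble averages", {
  toy <- makeToyAFF(eps = 1)
  m <- toy$model
  n <- nBeads(m)
  cmN <- filterContacts(contacts(m), c("N", "shared"))
  degree <- tabulate(c(cmN@i, cmN@j), nbins = n)

  # the native ensemble scores every residue at its contact degree
  sNative <- contactScore(list(m@refN), 1, cmN, n)
  expect_equal(sNative, as.numeric(degree))

  # a fully extended ensemble scores zero everywhere
  stretched <- cbind(0, seq(0, by = 50, length.out = n), 0)
  expect_equal(contactScore(list(stretched), 1, cmN, n), rep(0, n))

  # two frames weighted 0.75/0.25 (native vs none formed): every residue
  # scores 0.75 x its degree; hand-check the highest-degree residue
  sMix <- contactScore(list(m@refN, stretched), c(0.75, 0.25), cmN, n)
  expect_equal(sMix, 0.75 * as.numeric(degree))
  res <- which.max(degree)
  expect_equal(sMix[res], 0.75 * degree[res])

  # score bounds: 0 <= score <= native degree
  set.seed(9)
  frames <- lapply(1:6, function(k)
    m@refN + matrix(rnorm(length(m@refN), sd = 0.5), ncol = 3))
  s <- contactScore(frames, runif(6), cmN, n)
  expect_true(all(s >= 0 & s <= degree + 1e-12))

  expect_error(contactScore(list(m@refN[1:5, ]), 1, cmN, 5),
               "absent from the frames")
})

test_that("score tables carry per-ensemble columns and s.e.m.", {
  toy <- makeToyAFF(eps = 1)
  m <- toy$model
  n <- nBeads(m)
  maps <- list(N = filterContacts(contacts(m), c("N", "shared")),
               Nprime = filterContacts(contacts(m), c("Nprime", "shared")))
  mkSim <- function(seed) {
    set.seed(seed)
    list(frames = list(m@refN + matrix(rnorm(3 * n, sd = 0.2), ncol = 3)),
         weights = 1)
  }
  tab <- contactScoreTable(
    list(N = list(mkSim(1), mkSim(2)), Nprime = list(mkSim(3), mkSim(4))),
    maps, n)
  expect_named(tab, c("residue", "score_N", "sem_N", "score_Nprime",
                      "sem_Nprime"))
  expect_true(all(tab$sem_N >= 0))
})

test_that("candidate ranking applies the screen's selection rules", {
  # constructed score table: residue 2 loses all its contacts in the TPE,
  # residue 5 keeps them, residue 3 has the top difference but sits in the
  # binding site
  scores <- data.frame(residue = 1:6,
                       score_N = c(2, 4, 5, 3, 4, 1),
                       score_Nprime = c(2, 4, 5, 3, 4, 1),
                       score_TPE_fwd = c(1.5, 0.2, 0.2, 2.0, 3.9, 0.8),
                       score_TPE_rev = c(1.6, 0.1, 0.3, 2.1, 3.8, 0.9))
  cm <- new("ContactMap", i = c(1L, 2L, 2L, 3L, 4L, 5L),
            j = c(5L, 5L, 6L, 6L, 8L, 9L),
            r0 = rep(5, 6), eps = rep(1, 6), frameTag = rep("untagged", 6),
            cutoff = 8, minSeparation = 3L)
  rk <- rankCandidates(scores, cm, interfaceResidues = c(2, 5),
                       bindingSite = 3L)
  expect_equal(rk$residue[1], 2L)                  # top candidate
  expect_false(3L %in% rk$residue)                 # binding site excluded
  expect_equal(attr(rk, "negativeControl"), 5L)    # minimal change, buried

  # stability floor: residues above the floor are flagged out
  rk2 <- rankCandidates(scores, cm, interfaceResidues = c(2, 5),
                        bindingSite = 3L,
                        stability = c("2" = -0.5), stabilityFloor = -2)
  expect_false(2L %in% rk2$residue)

  # identical differences: ties break by residue index
  flat <- data.frame(residue = 1:4, score_N = 2, score_Nprime = 2,
                     score_TPE_fwd = 1, score_TPE_rev = 1)
  rkF <- rankCandidates(flat, cm, interfaceResidues = 1:4)
  expect_equal(rkF$residue, 1:4)
  expect_equal(attr(rkF, "negativeControl"), 1L)

  expect_error(rankCandidates(flat[0, ], cm, interfaceResidues = 1),
               "empty score table")
})

test_that("field mass and TSV export behave on 2-D grids", {
  sA <- stateDefinition("A", c(-Inf, -Inf), c(1, 1))
  P <- matrix(c(0.7, 0.1, 0.1, 0.1), 2, 2)
  f <- new("ProbabilityField", breaks = list(0:2, 0:2),
           mids = list(c(0.5, 1.5), c(0.5, 1.5)), P = P,
           G = -log(P), kT = 1, ensembleTag = "equilibrium")
  expect_equal(fieldMass(f, sA), 0.7)
  path <- tempfile(fileext = ".tsv")
  writeField(f, path)
  back <- utils::read.table(path, header = TRUE)
  expect_equal(sum(back$P), 1, tolerance = 1e-12)
})

test_that("the TPE field reveals a metastable intermediate only when present", {
  interiorMode <- function(thirdWell) {
    dw <- makeDoubleWell(barrier = 4, thirdWell = thirdWell)
    cfg <- weConfig("steady-state", binEdges = dw$binEdges,
                    walkersPerBin = 4, nIterations = 400,
                    initial = dw$stateA, target = dw$stateB,
                    seed = 61, burnIn = 0.3)
    arc <- runWE(dw$propagator, cfg)
    paths <- extractTPE(arc, burnIn = 0.3)
    f <- tpeField(paths, dw$binEdges, kT = 1)
    mids <- f@mids[[1]]
    # interior region between the state boundaries
    inner <- which(mids > -0.8 & mids < 0.8)
    P <- as.numeric(f@P)
    hasMode <- FALSE
    for (i in inner) {
      if (P[i] > P[i - 1] && P[i] > P[i + 1] && P[i] > 0.05 * max(P)) {
        # a genuine metastable intermediate stands well above the valleys
        # separating it from the states; transit noise does not
        valley <- max(min(P[min(inner):i]), min(P[i:max(inner)]))
        if (P[i] >= 3 * valley) hasMode <- TRUE
      }
    }
    hasMode
  }
  expect_true(interiorMode(TRUE))    # triple well: transient intermediate
  expect_false(interiorMode(FALSE))  # plain double well: none
})
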