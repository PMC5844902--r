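test_that("bin assignment is exhaustive, disjoint and uses [low, high) edges", {
  edges <- list(c(0, 1, 2, 3))
  b <- assignBins(matrix(c(0.5, 1.5, 2.5), ncol = 1), edges)
  expect_equal(as.integer(b), c(1L, 2L, 3L))

  # a coordinate exactly on an edge belongs to the bin it opens
  bEdge <- assignBins(matrix(c(1, 2), ncol = 1), edges)
  expect_equal(as.integer(bEdge), c(2L, 3L))

  # outermost bins absorb over/underflow
  bOut <- assignBins(matrix(c(-5, 99), ncol = 1), edges)
  expect_equal(as.integer(bOut), c(1L, 3L))

  # 100 random walkers partition exhaustively and disjointly
  set.seed(31)
  P <- matrix(runif(200, -2, 5), ncol = 2)
  b2 <- assignBins(P, list(c(0, 1, 2), c(0, 2, 4)))
  expect_length(b2, 100L)
  expect_true(all(b2 >= 1 & b2 <= 4))

  # non-finite coordinates are quarantined with an error record
  bq <- assignBins(matrix(c(0.5, NaN), ncol = 1), edges)
  expect_equal(attr(bq, "quarantined"), 2L)
  expect_true(is.na(bq[2]))
})

test_that("bin resampling conserves weight and splits/merges correctly", {
  r <- resampleBin(1.0, 4L)
  expect_equal(r$weight, rep(0.25, 4))
  expect_equal(r$origin, rep(1L, 4))

  set.seed(5)
  w5 <- runif(5)
  r5 <- resampleBin(w5, 4L)
  expect_length(r5$weight, 4L)
  expect_lt(abs(sum(r5$weight) - sum(w5)), 1e-12)

  expect_error(resampleBin(c(0.5, 0.5), 0L), "targetCount")
})

test_that("merge survivor frequencies follow the weight proportions", {
  set.seed(77)
  survived <- replicate(1e4, resampleBin(c(0.9, 0.1), 1L)$origin)
  frac <- mean(survived == 1L)
  expect_gt(frac, 0.89)
  expect_lt(frac, 0.91)
  # chi-squared goodness of fit on a 3-way merge cascade
  set.seed(78)
  w <- c(0.5, 0.3, 0.2)
  surv <- table(factor(replicate(1e4, resampleBin(w, 1L)$origin),
                       levels = 1:3))
  expect_gt(stats::chisq.test(surv, p = w)$p.value, 0.01)
})

test_that("history labels follow state visits and survive inheritance", {
  sA <- stateDefinition("i", -Inf, 0)
  sB <- stateDefinition("j", 2, Inf)
  lab <- NA_character_
  path <- c(-1, -0.5, 1, 1.5, 3, 1, -1)   # i, i, barrier, barrier, j, b, i
  got <- character(0)
  for (x in path) {
    lab <- updateHistoryLabels(lab, matrix(x, 1, 1), list(sA, sB))
    got <- c(got, lab)
  }
  expect_equal(got, c("i", "i", "i", "i", "j", "j", "i"))

  # walker never in any state stays unset
  expect_true(is.na(updateHistoryLabels(NA_character_, matrix(1, 1, 1),
                                        list(sA, sB))))
  # overlapping states are a configuration error
  expect_error(updateHistoryLabels("i", matrix(1, 1, 1),
                                   list(sA, stateDefinition("x", -1, 5))),
               "overlap")
})

test_that("recycling replaces target walkers with identical weights", {
  sB <- stateDefinition("B", 2, Inf)
  walkers <- list(coords = list(0.5, 3.0), weight = c(0.6, 0.4),
                  pcoord = matrix(c(0.5, 3.0), ncol = 1),
                  label = c("A", "B"))
  out <- recycleWalkers(walkers, sB, function(n) replicate(n, -1,
                                                           simplify = FALSE),
                        function(x) x, mode = "steady-state",
                        initialLabel = "A")
  expect_equal(out$flux, 0.4)
  expect_equal(out$walkers$weight, c(0.6, 0.4))   # weight inherited exactly
  expect_equal(out$walkers$coords[[2]], -1)
  expect_equal(out$walkers$label[2], "A")

  # no walker in target: identity with zero flux
  none <- list(coords = list(0.5), weight = 1,
               pcoord = matrix(0.5, 1, 1), label = "A")
  out0 <- recycleWalkers(none, sB, function(n) list(-1), function(x) x,
                         mode = "steady-state", initialLabel = "A")
  expect_equal(out0$flux, 0)
  expect_identical(out0$walkers, none)

  # equilibrium mode is the identity
  outE <- recycleWalkers(walkers, sB, function(n) list(-1), function(x) x,
                         mode = "equilibrium")
  expect_identical(outE$walkers, walkers)
  expect_equal(outE$flux, 0)
})

test_that("WE runs are deterministic and conserve weight in both modes", {
  dw <- makeDoubleWell(barrier = 3)
  for (mode in c("equilibrium", "steady-state")) {
    cfg <- weConfig(mode, binEdges = dw$binEdges, walkersPerBin = 4,
                    nIterations = 50, initial = dw$stateA,
                    target = dw$stateB, seed = 12)
    a <- runWE(dw$propagator, cfg)
    b <- runWE(dw$propagator, cfg)
    expect_identical(a@iterations, b@iterations)   # byte-identical archives
    expect_identical(a@flux, b@flux)
    expect_lt(max(abs(weightTotals(a) - 1)), 1e-12)
  }
})

test_that("equilibrium WE splits weight evenly between symmetric wells", {
  dw <- makeDoubleWell(barrier = 3)
  pA <- vapply(1:3, function(sd) {
    cfg <- weConfig("equilibrium", binEdges = dw$binEdges,
                    walkersPerBin = 4, nIterations = 400,
                    initial = dw$stateA, target = dw$stateB, seed = sd,
                    burnIn = 0.5)
    arc <- runWE(dw$propagator, cfg)
    h <- switchWE:::.archiveHistogram(arc, 1L)
    mids <- (dw$binEdges[[1]][-1] + head(dw$binEdges[[1]], -1)) / 2
    sum(h[mids < 0])
  }, numeric(1))
  sem <- stats::sd(pA) / sqrt(3)
  expect_lt(abs(mean(pA) - 0.5), 3 * max(sem, 0.02))
})

test_that("an unreachable target yields zero recycled flux", {
  dw <- makeDoubleWell(barrier = 200)   # effectively infinite barrier
  cfg <- weConfig("steady-state", binEdges = dw$binEdges,
                  walkersPerBin = 4, nIterations = 40,
                  initial = dw$stateA, target = dw$stateB, seed = 2)
  arc <- suppressWarnings(runWE(dw$propagator, cfg))
  expect_true(all(recycledFlux(arc) == 0))
})

test_that("every walker's lineage chains back to iteration zero", {
  dw <- makeDoubleWell(barrier = 3)
  cfg <- weConfig("steady-state", binEdges = dw$binEdges,
                  walkersPerBin = 4, nIterations = 60,
                  initial = dw$stateA, target = dw$stateB, seed = 8)
  arc <- runWE(dw$propagator, cfg)
  for (t in seq_len(nIterations(arc))) {
    it <- arc@iterations[[t]]
    if (t == 1L) {
      expect_true(all(it$parent == 0L))
    } else {
      prev <- arc@iterations[[t - 1L]]
      expect_true(all(it$parent >= 1L & it$parent <= length(prev$weight)))
    }
  }
  # the unset-label fraction decays as walkers first reach a state
  uf <- unsetLabelFraction(arc)
  expect_lt(uf[nIterations(arc)], uf[1] + 1e-12)
})
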