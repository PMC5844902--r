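test_that("energy terms take their closed-form values at reference points", {
  toy <- makeToyAFF(eps = 1.3)
  m <- toy$model
  # every contact of frame N sits at r0 in the N reference; N' contacts and
  # excluded volume make up the difference from -sum(eps)
  cpN <- filterContacts(contacts(m), c("N", "shared"))
  mN <- m
  mN@contactMap <- cpN
  expect_equal(contactEnergy(mN, m@refN), -sum(cpN@eps), tolerance = 1e-9)

  # fully stretched chain: all pair distances far beyond every well
  n <- nBeads(m)
  stretched <- cbind(0, seq(0, by = 50, length.out = n), 0)
  expect_equal(contactEnergy(m, stretched), 0, tolerance = 1e-10)
})

test_that("forces are the exact negative gradient of the energy", {
  toy <- makeToyAFF(eps = 1.3)
  m <- toy$model
  # also exercise the repulsive-core term of a mutated model
  mut <- applyMutation(m, mutationSpec(toy$candidateResidue))
  set.seed(7)
  tested <- 0
  while (tested < 20) {
    X <- m@refN + matrix(rnorm(length(m@refN), sd = runif(1, 0.05, 0.5)),
                         ncol = 3)
    # keep clear of the angle/dihedral collinearity guard, where the
    # kernel's regularized force intentionally departs from the raw
    # gradient
    if (guardMargin(m, X) < 0.02) next
    expect_lt(max(abs(fdForces(m, X) - modelForces(m, X))), 1e-4)
    expect_lt(max(abs(fdForces(mut, X) - modelForces(mut, X))), 1e-4)
    tested <- tested + 1
  }
})

test_that("overlapping beads raise a non-finite-energy error", {
  hp <- makeToyHairpin(nBeads = 16)
  X <- beadCoords(hp$structure)
  X[2, ] <- X[6, ] + 0.01
  expect_error(potentialEnergy(hp$model, X), "non-finite energy")
})

test_that("brownian step drift and determinism contracts hold", {
  cfg <- integratorConfig(units = "reduced", timestep = 0.01, D = 1,
                          tau = 0.01, sampleInterval = 0.01)
  x <- matrix(0, 5, 3)
  F <- matrix(2, 5, 3)
  # drift: subtracting the pure-noise step under the same seed leaves
  # exactly (D dt / kT) F
  set.seed(1); x1 <- brownianStep(x, F, cfg)
  set.seed(1); x0 <- brownianStep(x, 0 * F, cfg)
  expect_equal(x1 - x0, (cfg$D * cfg$timestep / cfg$kT) * F,
               tolerance = 1e-14)
  # same seed, same inputs -> identical trajectories
  set.seed(9); a <- Reduce(function(z, .) brownianStep(z, F, cfg), 1:50, x)
  set.seed(9); b <- Reduce(function(z, .) brownianStep(z, F, cfg), 1:50, x)
  expect_identical(a, b)
  # sanity bound
  cfgBig <- integratorConfig(units = "reduced", timestep = 0.01,
                             maxDisp = 0.01)
  expect_error(brownianStep(x, matrix(1e4, 5, 3), cfgBig),
               "timestep too large")
})

test_that("free diffusion reproduces the MSD closed form", {
  cfg <- integratorConfig(units = "reduced", timestep = 0.01, D = 1,
                          tau = 0.01, sampleInterval = 0.01)
  set.seed(11)
  n <- 1000; nsteps <- 200
  x <- matrix(0, n, 1)
  for (s in seq_len(nsteps)) x <- brownianStep(x, 0 * x, cfg)
  msd <- mean(x^2)
  expect_equal(msd, 2 * cfg$D * cfg$timestep * nsteps, tolerance = 0.05)
})

test_that("a harmonic coordinate equilibrates to the equipartition variance", {
  # overdamped particle in 0.5 k x^2, k = 4: var(x) = kT / k
  cfg <- integratorConfig(units = "reduced", timestep = 0.005, D = 1,
                          tau = 0.005, sampleInterval = 0.005)
  k <- 4
  set.seed(13)
  x <- matrix(0, 500, 1)
  for (s in 1:100) x <- brownianStep(x, -k * x, cfg)   # burn-in
  acc <- 0; nsamp <- 400
  for (s in seq_len(nsamp)) {
    for (r in 1:5) x <- brownianStep(x, -k * x, cfg)
    acc <- acc + mean(x^2)
  }
  expect_equal(acc / nsamp, cfg$kT / k, tolerance = 0.05)
})

test_that("stationary sampling of a quadratic well matches the Gaussian closed form", {
  cfg <- integratorConfig(units = "reduced", timestep = 0.005, D = 1,
                          tau = 0.005, sampleInterval = 0.005)
  k <- 2
  set.seed(17)
  x <- matrix(rnorm(200, sd = sqrt(cfg$kT / k)), 200, 1)
  samples <- numeric(0)
  for (s in 1:500) {
    for (r in 1:10) x <- brownianStep(x, -k * x, cfg)
    samples <- c(samples, x)
  }
  ks <- suppressWarnings(
    stats::ks.test(samples, "pnorm", sd = sqrt(cfg$kT / k)))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("segment propagation stores the configured samples and is reproducible", {
  dwCfg <- integratorConfig(units = "reduced", timestep = 0.002, tau = 0.1,
                            sampleInterval = 0.05)
  hp <- makeToyHairpin(nBeads = 16)
  prop <- goPropagator(setContactStrength(hp$model, 1), dwCfg)
  set.seed(3)
  seg <- runSegment(prop, hp$model@refN)
  expect_length(seg$samples, 2L)         # tau 0.1 / interval 0.05
  expect_equal(seg$times, c(0.05, 0.1))
  expect_identical(seg$samples[[2]], seg$end)

  # optional initial frame
  dwCfg2 <- integratorConfig(units = "reduced", timestep = 0.002,
                             tau = 0.1, sampleInterval = 0.05,
                             storeInitial = TRUE)
  prop2 <- goPropagator(setContactStrength(hp$model, 1), dwCfg2)
  set.seed(3)
  seg2 <- runSegment(prop2, hp$model@refN)
  expect_length(seg2$samples, 3L)
  expect_identical(seg2$samples[[1]], hp$model@refN)

  # single-step segment
  cfg1 <- integratorConfig(units = "reduced", timestep = 0.002,
                           tau = 0.002, sampleInterval = 0.002)
  prop1 <- goPropagator(setContactStrength(hp$model, 1), cfg1)
  set.seed(4)
  expect_length(runSegment(prop1, hp$model@refN)$samples, 1L)

  # byte-identical repeat under a fixed seed
  set.seed(5); a <- runSegment(prop, hp$model@refN)
  set.seed(5); b <- runSegment(prop, hp$model@refN)
  expect_identical(a, b)
  # invalid configs rejected
  expect_error(integratorConfig(units = "reduced", timestep = 0.03,
                                tau = 0.1), "integer multiple")
})

test_that("minimized RMSD matches oracles and is rigid-motion invariant", {
  set.seed(21)
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(12), 4, 3)
  expect_equal(rmsdKabsch(X, Y), quaternionRMSD(X, Y), tolerance = 1e-8)

  # symmetric in argument order
  expect_equal(rmsdKabsch(X, Y), rmsdKabsch(Y, X), tolerance = 1e-10)

  # identity and proper rigid motions
  expect_lt(rmsdKabsch(Y, Y), 1e-6)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- Y %*% t(R) + matrix(c(3, -2, 5), 4, 3, byrow = TRUE)
  expect_lt(rmsdKabsch(moved, Y), 1e-6)

  # independent package oracle on a larger cloud
  A <- matrix(rnorm(60), 20, 3); B <- matrix(rnorm(60), 20, 3)
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(B)), mobile = as.vector(t(A))))
  ref <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - B)^2)))
  expect_equal(rmsdKabsch(A, B), ref, tolerance = 1e-8)
})

test_that("progress coordinates are frame RMSDs with proper error handling", {
  toy <- makeToyAFF(eps = 1)
  prop <- toy$makePropagator()
  m <- toy$model
  p <- computeProgress(prop, m@refN)
  expect_lt(p[1], 1e-5)                               # N frame at reference
  expect_gt(p[2], 3)                                  # N' frame unfolded
  pN <- computeProgress(prop, m@refNprime)
  expect_lt(pN[2], 1e-5)
  expect_gt(pN[1], 3)
})
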