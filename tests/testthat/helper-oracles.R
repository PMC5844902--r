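# Shared oracle helpers.  Everything here is deliberately independent of the
# package's own computational paths (plain-R brute force, closed forms,
# quadrature), so that agreement is a genuine cross-check.

# central-difference gradient of the potential (oracle for modelForces)
fdForces <- function(model, X, h = 1e-4) {
  num <- matrix(0, nrow(X), 3)
  for (i in seq_len(nrow(X))) {
    for (c in 1:3) {
      Xp <- X; Xp[i, c] <- Xp[i, c] + h
      Xm <- X; Xm[i, c] <- Xm[i, c] - h
      num[i, c] <- -(potentialEnergy(model, Xp) -
                       potentialEnergy(model, Xm)) / (2 * h)
    }
  }
  num
}

# brute-force quaternion-free RMSD oracle: scan rotations is infeasible, so
# use the closed-form eigen decomposition route (quaternion method), a
# distinct algorithm from the package's SVD-based superposition
quaternionRMSD <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  R <- t(Xc) %*% Yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- R[1, 1] + R[2, 2] + R[3, 3]
  K[1, 2] <- K[2, 1] <- R[2, 3] - R[3, 2]
  K[1, 3] <- K[3, 1] <- R[3, 1] - R[1, 3]
  K[1, 4] <- K[4, 1] <- R[1, 2] - R[2, 1]
  K[2, 2] <- R[1, 1] - R[2, 2] - R[3, 3]
  K[2, 3] <- K[3, 2] <- R[1, 2] + R[2, 1]
  K[2, 4] <- K[4, 2] <- R[1, 3] + R[3, 1]
  K[3, 3] <- -R[1, 1] + R[2, 2] - R[3, 3]
  K[3, 4] <- K[4, 3] <- R[2, 3] + R[3, 2]
  K[4, 4] <- -R[1, 1] - R[2, 2] + R[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Xc^2) + sum(Yc^2) - 2 * lmax) / nrow(X)
  sqrt(max(0, msd))
}

# high-barrier MFPT of the double well by double-integral quadrature:
#   MFPT(-a -> a) = (1/D) int_{-a}^{a} dy e^{V(y)/kT} int_{-inf}^{y} dz e^{-V(z)/kT}
quadratureMFPT <- function(V, a, D = 1, kT = 1, lower = -6) {
  outer <- function(y) {
    vapply(y, function(yy) {
      exp(V(yy) / kT) *
        stats::integrate(function(z) exp(-V(z) / kT), lower, yy,
                         rel.tol = 1e-8)$value
    }, numeric(1))
  }
  stats::integrate(outer, -a, a, rel.tol = 1e-6)$value / D
}

# smallest |sin| margin of any angle/dihedral from the kernel's 0.1
# singularity guard; finite-difference gradient checks are only meaningful
# away from the guarded region
guardMargin <- function(model, X) {
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  m <- Inf
  ang <- model@angles
  for (r in seq_len(nrow(ang))) {
    a <- X[ang[r, 1], ] - X[ang[r, 2], ]
    b <- X[ang[r, 3], ] - X[ang[r, 2], ]
    ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    # the angle force is regularized everywhere below sin = 0.1, so the
    # configuration must sit strictly above the floor
    m <- min(m, sqrt(max(0, 1 - ct^2)) - 0.1)
  }
  dh <- model@dihedrals
  for (r in seq_len(nrow(dh))) {
    b1 <- X[dh[r, 2], ] - X[dh[r, 1], ]
    b2 <- X[dh[r, 3], ] - X[dh[r, 2], ]
    b3 <- X[dh[r, 4], ] - X[dh[r, 3], ]
    s1 <- sqrt(sum(cr(b1, b2)^2) / (sum(b1^2) * sum(b2^2)))
    s2 <- sqrt(sum(cr(b2, b3)^2) / (sum(b2^2) * sum(b3^2)))
    m <- min(m, abs(s1 - 0.1), abs(s2 - 0.1))
  }
  m
}

# discrete two-state Markov propagator satisfying the segment contracts:
# position flips 1 <-> 2 with the given per-segment probabilities
setClass("MarkovPropagator",
         representation(p12 = "numeric", p21 = "numeric", config = "list"))
setMethod("runSegment", "MarkovPropagator", function(propagator, coords) {
  x <- coords
  if (x == 1) {
    if (stats::runif(1) < propagator@p12) x <- 2
  } else if (stats::runif(1) < propagator@p21) x <- 1
  list(end = x, samples = list(x), times = propagator@config$tau)
})
setMethod("computeProgress", "MarkovPropagator",
          function(propagator, coords) as.numeric(coords))
setMethod("progressDim", "MarkovPropagator", function(propagator) 1L)
setMethod("initialConfigurations", "MarkovPropagator",
          function(propagator, n) replicate(n, 1, simplify = FALSE))

markovPropagator <- function(p12, p21 = p12, tau = 1) {
  new("MarkovPropagator", p12 = p12, p21 = p21, config = list(tau = tau))
}

# hand-built archive with explicit per-iteration records (for the scripted
# TPE and rate-arithmetic tests); walkers is a list of iteration records
syntheticArchive <- function(iterations, mode = "steady-state", flux = NULL,
                             tau = 1, initial = NULL, target = NULL,
                             burnIn = 0) {
  if (is.null(flux))
    flux <- vapply(iterations, function(it)
      sum(it$weight[it$recycled]), numeric(1))
  new("WEArchive", mode = mode,
      config = list(burnIn = burnIn, initial = initial, target = target,
                    binEdges = list(seq(0, 10, 1))),
      iterations = iterations,
      sumWeight = vapply(iterations, function(it) sum(it$weight),
                         numeric(1)),
      flux = flux, tau = tau)
}

# single-walker lineage archive from a scripted progress-coordinate path
# (one walker per iteration, parent chains linking them)
scriptedArchive <- function(pcoords, recycledAt = integer(0),
                            initial, target, weight = 1) {
  its <- lapply(seq_along(pcoords), function(t) {
    list(weight = weight, pcoord = matrix(pcoords[t], 1, 1),
         label = NA_character_,
         parent = if (t == 1L) 0L else 1L,
         parentRecycled = FALSE,
         recycled = t %in% recycledAt,
         binCount = 1L)
  })
  syntheticArchive(its, initial = initial, target = target)
}
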