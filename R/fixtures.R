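#' @include ensemble.R calibrate.R
NULL

# session cache for calibrated fixture strengths (keyed by spec string)
.fixtureCache <- new.env(parent = emptyenv())

#' 1-D diffusive well propagator
#'
#' A single overdamped Brownian particle in a closed-form double or triple
#' well; the progress coordinate is the position itself.  Stands in for
#' switching systems of varying barrier height with analytically tractable
#' kinetics.
#'
#' @slot h barrier height (kT units).
#' @slot a half well separation (minima at -a and +a; the triple well adds a
#'   minimum at 0).
#' @slot type 2L (double) or 3L (triple).
#' @slot config integrator settings (dt, D, kT, tau, sampleEvery, x0, tau).
#' @export
setClass("WellPropagator",
         representation(h = "numeric", a = "numeric", type = "integer",
                        config = "list"))

#' @rdname runSegment
#' @export
setMethod("runSegment", "WellPropagator", function(propagator, coords) {
  cf <- propagator@config
  out <- cpp_dw_propagate(as.numeric(coords), cf$nsteps, cf$timestep, cf$D,
                          cf$kT, propagator@h, propagator@a,
                          propagator@type, cf$sampleEvery)
  list(end = out$end, samples = as.list(out$samples),
       times = seq_along(out$samples) * cf$sampleEvery * cf$timestep)
})

#' @rdname computeProgress
#' @export
setMethod("computeProgress", "WellPropagator",
          function(propagator, coords) as.numeric(coords))

#' @rdname progressDim
#' @export
setMethod("progressDim", "WellPropagator", function(propagator) 1L)

#' @rdname initialConfigurations
#' @export
setMethod("initialConfigurations", "WellPropagator",
          function(propagator, n)
            replicate(n, propagator@config$x0, simplify = FALSE))

setMethod("show", "WellPropagator", function(object) {
  cat(sprintf("WellPropagator: %s well, barrier %g kT, minima at +-%g\n",
              if (object@type == 3L) "triple" else "double",
              object@h, object@a))
})

#' Build a 1-D double-well (or triple-well) fixture
#'
#' The double well is `V(x) = h ((x/a)^2 - 1)^2` (minima at -a and +a,
#' barrier `h` at 0); the triple well is `V(x) = 6.75 h (x/a)^2 ((x/a)^2 -
#' 1)^2` (equal minima at -a, 0, +a, barrier `h` between neighbours).  The
#' triple well is the stand-in for switching with a metastable on-pathway
#' intermediate.  Reduced units: `kT = 1`.
#'
#' @param barrier barrier height `h` in kT (> 0 for metastability; 0 gives
#'   free diffusion, on which state definition fails as designed).
#' @param wellSeparation distance between the outer minima (`2a`).
#' @param D diffusion coefficient.
#' @param thirdWell add the central metastable well.
#' @param dt integration timestep.
#' @param tau WE segment length.
#' @param kT thermal energy (reduced default 1).
#' @param binWidth WE bin width as a fraction of `a`.
#' @return list with `propagator` (a [WellPropagator-class] starting at
#'   `-a`), `stateA`/`stateB` ([StateDefinition-class]s with boundaries at
#'   the outer minima, i.e. the modes of the stationary distribution),
#'   `binEdges`, `V` (the potential function), and the spec parameters.
#' @examples
#' dw <- makeDoubleWell(barrier = 4)
#' dw$V(0) - dw$V(1)   # barrier height
#' @export
makeDoubleWell <- function(barrier = 5, wellSeparation = 2, D = 1,
                           thirdWell = FALSE, dt = 1e-3, tau = 0.05,
                           kT = 1, binWidth = 0.1) {
  stopifnot(barrier >= 0, wellSeparation > 0)
  a <- wellSeparation / 2
  type <- if (thirdWell) 3L else 2L
  cf <- list(timestep = dt, D = D, kT = kT, tau = tau,
             sampleEvery = as.integer(round(tau / dt)),
             nsteps = as.integer(round(tau / dt)), x0 = -a)
  prop <- new("WellPropagator", h = barrier, a = a, type = type,
              config = cf)
  edges <- seq(-1.6 * a, 1.6 * a, by = binWidth * a)
  list(propagator = prop,
       stateA = stateDefinition("A", -Inf, -a),
       stateB = stateDefinition("B", a, Inf),
       stateI = if (thirdWell)
         stateDefinition("I", -0.15 * a, 0.15 * a) else NULL,
       binEdges = list(edges),
       V = function(x) vapply(x, cpp_well_V, numeric(1), h = barrier,
                              a = a, type = type),
       barrier = barrier, a = a, D = D, kT = kT, dt = dt, tau = tau)
}

#' Brute-force rate oracle for a 1-D well fixture
#'
#' Runs plain, unbiased Brownian dynamics from the initial minimum, records
#' the first-passage time to the far state's boundary, resets, and repeats.
#' The rate is `1 / MFPT` with the s.e.m. propagated from the event-time
#' dispersion.  This code path shares nothing with the WE engine, so
#' agreement between the two is a genuine cross-check.
#'
#' @param dw a fixture from [makeDoubleWell()].
#' @param nEvents number of independent events to harvest (>= 50).
#' @param seed RNG seed.
#' @param reverse measure B -> A instead of A -> B.
#' @param maxSteps step budget; exhausted budget returns fewer events with
#'   a partial-estimate warning.
#' @return list with `rate`, `sem`, `mfpt`, `mfptSem`, `times`,
#'   `totalTime` (aggregate simulated time).
#' @export
bruteForceRate <- function(dw, nEvents = 200, seed = 1, reverse = FALSE,
                           maxSteps = 5e8) {
  stopifnot(nEvents >= 50)
  set.seed(seed)
  x0 <- if (reverse) dw$a else -dw$a
  tg <- if (reverse) -dw$a else dw$a
  times <- cpp_dw_fpt(x0, tg, as.integer(nEvents), dw$dt, dw$D, dw$kT,
                      dw$barrier, dw$a, dw$propagator@type, maxSteps)
  if (length(times) < nEvents)
    warning(sprintf("partial estimate: %d of %d events within budget",
                    length(times), nEvents))
  m <- mean(times)
  msem <- stats::sd(times) / sqrt(length(times))
  list(rate = 1 / m, sem = msem / m^2, mfpt = m, mfptSem = msem,
       times = times, totalTime = sum(times))
}

#' Brute-force stationary histogram for a 1-D well fixture
#'
#' Long unbiased trajectory, occupancy binned on the fixture's WE bin
#' edges; the independent oracle for WE unbiasedness checks.
#'
#' @param dw a fixture from [makeDoubleWell()].
#' @param nSteps trajectory length in steps.
#' @param sampleEvery record every this many steps.
#' @param seed RNG seed.
#' @return normalized probability per WE bin.
#' @export
bruteForceHistogram <- function(dw, nSteps = 2e7, sampleEvery = 20,
                                seed = 1) {
  set.seed(seed)
  edges <- dw$binEdges[[1L]]
  counts <- cpp_dw_histogram(-dw$a, nSteps, dw$dt, dw$D, dw$kT,
                             dw$barrier, dw$a, dw$propagator@type,
                             as.integer(sampleEvery), edges)
  # interior breaks partition into length(edges)+1 cells; fold the
  # absorbing outer cells into the outermost bins to match assignBins()
  m <- length(edges) - 1L
  p <- counts[2:(m + 1L)]
  p[1L] <- p[1L] + counts[1L]
  p[m] <- p[m] + counts[m + 2L]
  p / sum(p)
}

# ---- beta-hairpin geometry ------------------------------------------------

# Parent fold of the miniature AFF switch: a scaffold hairpin (strands A1,
# A2, outer positions of a three-stranded sheet) plus a docking hairpin B
# whose bottom strand occupies the sheet's central slot and whose top
# strand packs above it.  The central slot is sterically singular, so in
# the dual-frame construct the duplicated copy of B and the original B
# cannot both dock: the frames fold mutually exclusively through excluded
# volume alone.  Coordinates rounded to 3 decimals for exact PDB
# round-trips.
.parentFoldCoords <- function(wtLength = 20L, rise = 3.45, lat = 4.4,
                              topZ = 4.8, pleat = 0.5) {
  stopifnot(wtLength %% 4 == 0, wtLength >= 16)
  q <- wtLength / 4L
  ymax <- (q - 1) * rise
  pos <- function(i) {
    if (i <= q)                      # A1: outer strand, x = 0
      c(0, (i - 1) * rise, pleat * (i %% 2))
    else if (i <= 2 * q)             # A2: outer strand, x = 2 lat
      c(2 * lat, ymax - (i - q - 1) * rise, pleat * (i %% 2))
    else if (i <= 3 * q)             # B bottom: central sheet strand
      c(lat, (i - 2 * q - 1) * rise, pleat * ((i + 1) %% 2))
    else                             # B top: packs above the centre
      c(lat, ymax - (i - 3 * q - 1) * rise, topZ + pleat * (i %% 2))
  }
  round(t(vapply(seq_len(wtLength), pos, numeric(3))), 3)
}

# extended (denatured-reference) chain along y with a small zig-zag;
# rounded to 3 decimals like every fixture geometry
.extendedCoords <- function(nBeads, rise = 3.6) {
  round(t(vapply(seq_len(nBeads), function(i)
    c(0.9 * (i %% 2), (i - 1) * rise, 0), numeric(3))), 3)
}

# state-restricted configuration pool from an equilibrium archive with
# stored coordinates: the pre-equilibrated initial ensemble for
# steady-state runs
statePool <- function(archive, state, burnIn = NULL) {
  ensembleFrames(archive, state, burnIn)
}

# two antiparallel strands of n/2 beads, 5 A apart, with a 0.8 A pleat;
# coordinates rounded to 3 decimals so PDB round-trips are exact
.hairpinCoords <- function(nBeads, strandSep = 5.0, rise = 3.45,
                           pleat = 0.8) {
  stopifnot(nBeads %% 2 == 0, nBeads >= 8)
  half <- nBeads / 2L
  A <- t(vapply(seq_len(half), function(i)
    c(0, (i - 1) * rise, pleat * (i %% 2)), numeric(3)))
  B <- t(vapply((half + 1L):nBeads, function(j)
    c(strandSep, (nBeads - j) * rise, pleat * ((j + 1) %% 2)), numeric(3)))
  round(rbind(A, B), 3)
}

#' Build a two-state beta-hairpin folder fixture
#'
#' A `nBeads`-bead antiparallel hairpin whose native contacts are the
#' cross-strand pairs; with calibrated contact strengths it folds
#' two-state.  Real units (kcal/mol, Angstrom; time in reduced units), so
#' stabilities are directly comparable to experimental folding free
#' energies.  The fixture wires two WE stability estimators in: the default
#' `stabilityFun(eps, seed)` (suitable for [calibrateContactStrength()])
#' pre-equilibrates the state ensembles with an equilibrium run and
#' combines opposing steady-state folding/unfolding rates through
#' [stabilityFromRates()], which stays well-conditioned for strongly
#' stable folders; `eqStabilityFun` reads populations off a long
#' equilibrium run directly — the two routes cross-validate each other.
#'
#' @param nBeads chain length (even, >= 8; default 16).
#' @param eps uniform contact strength (kcal/mol); `NA` leaves the map at
#'   the uncalibrated default 1.
#' @param temperature kelvin.
#' @param nIterations,walkersPerBin WE settings of the stability estimator.
#' @param calibrate unused placeholder kept for symmetry with
#'   [makeToyAFF()]; calibration is explicit via the returned
#'   `stabilityFun`.
#' @return list with `structure`, `contacts`, `model` (degenerate
#'   [AFFModel-class], i.e. the plain folder), `pdbText`, `binEdges`,
#'   `folded`/`unfolded` state definitions, `kT`, `makePropagator(eps)` and
#'   `stabilityFun(eps, seed)`.
#' @export
makeToyHairpin <- function(nBeads = 16L, eps = 1.0, temperature = 293.15,
                           nIterations = 800L, walkersPerBin = 4L,
                           calibrate = FALSE) {
  X <- .hairpinCoords(nBeads)
  s <- beadStructure(X)
  cm <- computeNativeContacts(s, cutoff = 8.0, minSeparation = 3L,
                              eps = if (is.na(eps)) 1.0 else eps)
  model <- buildAFFModel(s, cm, dupRange = NULL, linkerLength = 0L,
                         units = "real")
  kT <- R_KCAL * temperature
  edges <- seq(0, 14, by = 0.5)
  folded <- stateDefinition("folded", -Inf, 2.5)
  unfolded <- stateDefinition("unfolded", 5.5, Inf)
  extended <- .extendedCoords(nBeads)
  makePropagator <- function(epsVal, tau = 0.5, start = NULL,
                             pool = NULL) {
    m <- setContactStrength(model, epsVal)
    cf <- integratorConfig(temperature = temperature, timestep = 0.002,
                           D = 1, tau = tau, sampleInterval = tau,
                           units = "real", maxDisp = 2.0)
    cf$initialCoords <- start
    cf$initialPool <- pool
    goPropagator(m, cf)
  }
  eqStabilityFun <- function(epsVal, seed = 101L, iters = nIterations,
                             burnIn = 0.3, method = "region") {
    prop <- makePropagator(epsVal)
    cfg <- weConfig("equilibrium", binEdges = list(edges),
                    walkersPerBin = walkersPerBin, nIterations = iters,
                    initial = folded, target = unfolded, seed = seed,
                    burnIn = burnIn)
    arc <- runWE(prop, cfg)
    estimateStability(arc, folded, unfolded, kT, method = method)@dG
  }
  # the default estimator is the opposing-steady-state route (the better
  # conditioned one for strongly stable folders): equilibrium WE
  # pre-equilibrates the two state ensembles, then folding and unfolding
  # runs recycle into weighted draws from those pools, and the rate ratio
  # gives dG
  stabilityFun <- function(epsVal, seed = 101L, eqIters = 400L,
                           ssIters = 400L, burnIn = 0.4) {
    prop <- makePropagator(epsVal)
    eqCfg <- weConfig("equilibrium", binEdges = list(edges),
                      walkersPerBin = walkersPerBin, nIterations = eqIters,
                      initial = folded, target = unfolded, seed = seed,
                      storeCoords = TRUE, burnIn = burnIn)
    eq <- runWE(prop, eqCfg)
    poolF <- statePool(eq, folded)
    poolU <- statePool(eq, unfolded)
    propU <- makePropagator(epsVal, pool = poolF)
    cfgU <- weConfig("steady-state", binEdges = list(edges),
                     walkersPerBin = walkersPerBin, nIterations = ssIters,
                     initial = folded, target = unfolded,
                     seed = seed + 1L, burnIn = burnIn)
    kU <- estimateRate(runWE(propU, cfgU))
    propF <- makePropagator(epsVal, pool = poolU)
    cfgF <- weConfig("steady-state", binEdges = list(edges),
                     walkersPerBin = walkersPerBin, nIterations = ssIters,
                     initial = unfolded, target = folded,
                     seed = seed + 2L, burnIn = burnIn)
    kF <- estimateRate(runWE(propF, cfgF))
    stabilityFromRates(kF, kU, kT)@dG
  }
  list(structure = s, contacts = cm, model = model,
       pdbText = writeStructurePDB(s), binEdges = list(edges),
       folded = folded, unfolded = unfolded, kT = kT,
       extendedCoords = extended,
       makePropagator = makePropagator, stabilityFun = stabilityFun,
       eqStabilityFun = eqStabilityFun)
}

#' Build the miniature dual-frame AFF fixture
#'
#' The 20-bead parent fold is a scaffold hairpin (residues 1-10, the two
#' outer strands of a three-stranded sheet) plus a docking hairpin
#' (residues 11-20) whose bottom strand occupies the sheet's central slot
#' (see the construction notes in the source).  Duplicating residues 11-20
#' and prepending them through a 2-residue linker gives a 32-bead
#' construct: frame N is the original fold (construct 13-32), frame N' the
#' circular-permutant fold (construct 1-10 plus the shared scaffold
#' 13-22).  The central docking slot holds exactly one copy, so the frames
#' fold mutually exclusively through excluded volume.  Reduced units
#' (kT = 1).
#'
#' The default contact strength (0.80) is the value fixed when the fixture
#' was defined: it makes each frame of the construct a clear two-state
#' folder (about 80-90 percent folded from its own reference, i.e. a frame
#' stability of roughly -2 kT, the stability-floor regime of the design
#' criteria) while keeping switching samplable; `calibrate = TRUE`
#' re-derives a strength from the isolated parent's stability via
#' [calibrateToyAFFParent()] instead.
#'
#' Interface landmarks used by the design screen: switching kinetics in
#' this construct are direction-polarized — the A1-side scaffold contacts
#' break in the N to N' transition paths while the A2-side contacts break
#' in the reverse ones — so, exactly like the primed/unprimed mutation
#' pairs of the design strategy, the promising mutation is the *pair* of
#' top per-direction residues: `candidateResidue` (construct 15, the A1
#' scaffold residue with the largest forward score difference) together
#' with construct 20 (its A2 counterpart for the reverse direction),
#' returned as `candidatePair`; the two occupy the top of the combined
#' ranking, their order subject to TPE sampling noise.
#' The `negativeControlResidue` (construct 30, the core of the orphan
#' docking hand) keeps its contacts — the orphan hand stays internally
#' structured through switching — so its mutation destabilizes ground and
#' transition states alike and leaves both rates unchanged.
#'
#' @param wtLength parent length (multiple of 4; default 20).
#' @param dupRange duplicated parent interval (default 11-20, the docking
#'   hairpin).
#' @param linkerLength linker residues (default 2).
#' @param targetDG parent-fold stability target used when
#'   `calibrate = TRUE` (kT).
#' @param eps explicit uniform contact strength (overrides everything).
#' @param calibrate re-derive the strength by calibration (slow; cached
#'   per session).
#' @param tau WE segment length (reduced time).
#' @return list with `model` ([AFFModel-class]), `eps`, `makePropagator()`,
#'   `stateN`/`stateNprime`/`bothFolded` state definitions, 2-D `binEdges`,
#'   `pdbText` (construct reference as PDB), `candidateResidue`,
#'   `negativeControlResidue`, `interfaceResidues`, `kT`.
#' @export
makeToyAFF <- function(wtLength = 20L, dupRange = c(11L, 20L),
                       linkerLength = 2L, targetDG = -3, eps = NULL,
                       calibrate = FALSE, tau = 1.0) {
  X <- .parentFoldCoords(wtLength)
  s <- beadStructure(X)
  # the parent sheet pairs outer strands across ~8.8 A, so the native
  # contact cutoff is 9 A for this fixture (config-exposed elsewhere)
  cm <- computeNativeContacts(s, cutoff = 9.0, minSeparation = 3L)
  if (is.null(eps) && !calibrate) eps <- .TOYAFF_EPS
  if (is.null(eps)) {
    key <- paste("toyaff", wtLength, paste(dupRange, collapse = "-"),
                 linkerLength, targetDG, sep = "_")
    if (is.null(.fixtureCache[[key]])) {
      cal <- calibrateToyAFFParent(s, cm, targetDG)
      .fixtureCache[[key]] <- cal$eps
    }
    eps <- .fixtureCache[[key]]
  }
  model <- buildAFFModel(s, cm, dupRange = dupRange,
                         linkerLength = linkerLength, units = "reduced")
  model <- setContactStrength(model, eps)
  ndup <- dupRange[2L] - dupRange[1L] + 1L
  offset <- ndup + linkerLength
  makePropagator <- function(m = model, startFrame = c("N", "Nprime"),
                             pool = NULL) {
    startFrame <- match.arg(startFrame)
    cf <- integratorConfig(units = "reduced", timestep = 0.004, D = 1,
                           tau = tau, sampleInterval = tau, kT = 1,
                           maxDisp = 2.0)
    cf$initialCoords <- if (startFrame == "N") m@refN else m@refNprime
    cf$initialPool <- pool
    goPropagator(m, cf)
  }
  fThr <- 2.0; uThr <- 4.0
  edges2 <- list(seq(0, 12, by = 2.0), seq(0, 12, by = 2.0))
  list(model = model, eps = eps, parentStructure = s, parentContacts = cm,
       makePropagator = makePropagator,
       stateN = stateDefinition("N", c(-Inf, uThr), c(fThr, Inf)),
       stateNprime = stateDefinition("Nprime", c(uThr, -Inf),
                                     c(Inf, fThr)),
       bothFolded = stateDefinition("both", c(-Inf, -Inf), c(fThr, fThr)),
       binEdges = edges2,
       pdbText = writeStructurePDB(
         beadStructure(round(model@refN, 3))),
       candidateResidue = offset + 3L,
       candidatePair = c(offset + 3L, offset + 8L),
       negativeControlResidue = offset + ndup + 8L,
       # the structured packing interface of the reference fold (the
       # duplicated copy dangles unfolded there and is not part of it)
       interfaceResidues = offset + seq_len(wtLength),
       fwdBinEdges = list(c(0, 2, 4, 12), seq(0, 12, 1)),
       revBinEdges = list(seq(0, 12, 1), c(0, 2, 4, 12)),
       kT = 1, tau = tau)
}

#' Calibrate the miniature AFF parent fold to a target stability
#'
#' Equilibrium-WE stability of the isolated parent as a function of the
#' uniform contact strength, bisected to the target.  [makeToyAFF()]\'s
#' default strength is the value this one-off calibration produced for the
#' default target; pass `calibrate = TRUE` there to re-derive it.
#'
#' @param s parent [BeadStructure-class].
#' @param cm parent [ContactMap-class].
#' @param targetDG target folding free energy, kT.
#' @return the [calibrateContactStrength()] result.
#' @export
calibrateToyAFFParent <- function(s, cm, targetDG = -3) {
  parent <- buildAFFModel(s, cm, dupRange = NULL, linkerLength = 0L,
                          units = "reduced")
  edges <- seq(0, 14, by = 0.5)
  folded <- stateDefinition("folded", -Inf, 2.5)
  unfolded <- stateDefinition("unfolded", 5.5, Inf)
  stab <- function(epsVal) {
    m <- setContactStrength(parent, epsVal)
    cf <- integratorConfig(units = "reduced", timestep = 0.002,
                           D = 1, tau = 0.5, sampleInterval = 0.5,
                           kT = 1, maxDisp = 2.0)
    prop <- goPropagator(m, cf)
    cfg <- weConfig("equilibrium", binEdges = list(edges),
                    walkersPerBin = 4L, nIterations = 300L,
                    initial = folded, target = unfolded, seed = 97L,
                    burnIn = 0.4)
    # a folder so stable that the unfolded state never accumulates weight
    # is beyond the measurable range: report it as such so bracketing
    # still works
    tryCatch(
      estimateStability(runWE(prop, cfg), folded, unfolded, kT = 1)@dG,
      error = function(e) -Inf)
  }
  calibrateContactStrength(stab, targetDG, tolerance = 0.3,
                           epsBounds = c(0.45, 1.0))
}

# uniform contact strength of the default miniature AFF switch: the value
# at which the isolated parent fold has dG_fold = -3 kT (one-off
# calibration of the generator; see calibrateToyAFFParent)
.TOYAFF_EPS <- 0.80

#' Equilibrium WE run of the miniature switch
#'
#' Starts from the frame-N reference and lets the weighted ensemble relax
#' across both folds; the resulting archive supplies the equilibrium
#' surface, the mutual-exclusivity check, the state-restricted pools and
#' (through its stored final walker set) warm starts for steady-state
#' switching runs.
#'
#' @param toy fixture from [makeToyAFF()].
#' @param model model to simulate (default the fixture's; pass a mutant).
#' @param nIterations WE iterations.
#' @param seed RNG seed.
#' @param storeCoords keep configurations (needed for contact scores).
#' @param startFrame start from the frame-N or frame-Nprime reference.
#' @return a [WEArchive-class].
#' @export
toyEquilibrium <- function(toy, model = toy$model, nIterations = 300L,
                           seed = 1L, storeCoords = FALSE,
                           startFrame = "N") {
  prop <- toy$makePropagator(model, startFrame = startFrame)
  cfg <- weConfig("equilibrium", binEdges = toy$binEdges,
                  walkersPerBin = 4L, nIterations = nIterations,
                  initial = toy$stateN, target = toy$stateNprime,
                  seed = seed, storeCoords = storeCoords, burnIn = 0.5)
  runWE(prop, cfg)
}

#' Directional switching rates of the miniature switch
#'
#' Runs `nRuns` independent steady-state WE simulations per direction at
#' the fixture's matched switching protocol: each direction warm-starts
#' from the final walker set of an equilibrium archive begun in its own
#' initial fold (the pre-equilibrated initial states of the standard
#' protocol), and bins finely along the incoming frame's RMSD — the slow
#' docking coordinate — with three coarse bins (folded / intermediate /
#' far) along the other frame's RMSD.
#'
#' @param toy fixture from [makeToyAFF()].
#' @param model model to simulate (default the fixture's; pass a mutant).
#' @param eqN,eqNp equilibrium archives started from the N and N' folds
#'   (defaults: fresh [toyEquilibrium()] runs of the simulated model).
#' @param nRuns independent runs per direction (>= 2 for an s.e.m.).
#' @param itersFwd,itersRev WE iterations per steady-state run (the
#'   forward direction's longer transit gets longer runs).
#' @param walkersPerBin target walkers per occupied bin.
#' @param wpbFwd,wpbRev per-direction overrides of `walkersPerBin` (the
#'   forward direction tolerates a leaner ensemble; the reverse
#'   comparisons benefit from the fuller one).
#' @param seed base RNG seed; each run uses a distinct offset.
#' @param burnIn burn-in fraction for the rate estimates.
#' @param storeCoords keep configurations (for TPE scoring).
#' @return list with `fwd` and `rev` [RateEstimate-class]s (N to N' and
#'   N' to N) and the underlying archives (`fwdArcs`, `revArcs`).
#' @export
toySwitchRates <- function(toy, model = toy$model, eqN = NULL, eqNp = NULL,
                           nRuns = 2L, itersFwd = 350L, itersRev = 250L,
                           walkersPerBin = 4L, wpbFwd = walkersPerBin,
                           wpbRev = walkersPerBin, seed = 40L,
                           burnIn = 0.5, storeCoords = FALSE) {
  if (is.null(eqN))
    eqN <- toyEquilibrium(toy, model, seed = seed + 900L)
  if (is.null(eqNp))
    eqNp <- toyEquilibrium(toy, model, seed = seed + 901L,
                           startFrame = "Nprime")
  oneDir <- function(startFrame, initial, target, edges, warm, iters,
                     seeds, wpb) {
    prop <- toy$makePropagator(model, startFrame = startFrame)
    lapply(seeds, function(sd) {
      cfg <- weConfig("steady-state", binEdges = edges,
                      walkersPerBin = wpb,
                      nIterations = iters, initial = initial,
                      target = target, seed = sd, burnIn = burnIn,
                      initialWalkers = warm, storeCoords = storeCoords)
      runWE(prop, cfg)
    })
  }
  fwdArcs <- oneDir("N", toy$stateN, toy$stateNprime, toy$fwdBinEdges,
                    eqN@config$finalState, itersFwd,
                    seed + 2L * seq_len(nRuns) - 1L, wpbFwd)
  revArcs <- oneDir("Nprime", toy$stateNprime, toy$stateN,
                    toy$revBinEdges, eqNp@config$finalState, itersRev,
                    seed + 2L * seq_len(nRuns), wpbRev)
  list(fwd = estimateRate(fwdArcs), rev = estimateRate(revArcs),
       fwdArcs = fwdArcs, revArcs = revArcs)
}
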