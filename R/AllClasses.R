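# Central S4 containers.  Heavier per-operation documentation lives with the
# constructors and operations in the module files.

#' C-alpha bead model of one chain
#'
#' One bead per residue, placed at the C-alpha position.  Residue indices are
#' 1-based, strictly increasing and contiguous.
#'
#' @slot coords numeric n x 3 matrix of bead positions (Angstrom).
#' @slot residueIndex integer vector of 1-based residue indices.
#' @slot residueName character vector of 3-letter residue codes.
#' @seealso [loadStructure()], [computeNativeContacts()]
#' @export
setClass("BeadStructure",
  representation(coords = "matrix",
                 residueIndex = "integer",
                 residueName = "character"))

setValidity("BeadStructure", function(object) {
  n <- nrow(object@coords)
  if (n < 4L) return("chain_length must be >= 4")
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  if (!all(is.finite(object@coords))) return("all coordinates must be finite")
  if (length(object@residueIndex) != n || length(object@residueName) != n)
    return("residueIndex/residueName length must match coords rows")
  if (!identical(object@residueIndex,
                 seq.int(object@residueIndex[1L], length.out = n)))
    return("residue indices must be strictly increasing and contiguous")
  TRUE
})

#' Native contact map
#'
#' Residue pairs (i, j), j > i, in contact in the native structure, with the
#' native pair distance `r0` (the position of each contact well's minimum) and
#' well depth `eps`.  In dual-frame AFF models every pair carries a frame tag:
#' `"N"` (N-frame only), `"Nprime"` (N'-frame only) or `"shared"` (lies
#' entirely within the segment common to both frames and is counted once).
#' Maps built directly from a single structure are tagged `"untagged"`.
#'
#' @slot i,j integer vectors of 1-based residue indices, `j > i`.
#' @slot r0 numeric vector of native pair distances (Angstrom).
#' @slot eps numeric vector of well depths (energy unit), >= 0.
#' @slot frameTag character vector, one of `"N"`, `"Nprime"`, `"shared"`,
#'   `"untagged"`.
#' @slot cutoff,minSeparation the distance cutoff (Angstrom) and minimum
#'   sequence separation used to define the map.
#' @export
setClass("ContactMap",
  representation(i = "integer", j = "integer", r0 = "numeric",
                 eps = "numeric", frameTag = "character",
                 cutoff = "numeric", minSeparation = "integer"))

setValidity("ContactMap", function(object) {
  m <- length(object@i)
  if (length(object@j) != m || length(object@r0) != m ||
      length(object@eps) != m || length(object@frameTag) != m)
    return("all per-pair slots must have equal length")
  if (m == 0L) return(TRUE)
  if (any(object@j <= object@i)) return("pairs must satisfy j > i")
  if (any(object@j - object@i < object@minSeparation))
    return("pairs must satisfy |i - j| >= minSeparation")
  if (any(object@r0 <= 0)) return("r0 must be positive")
  if (any(object@eps < 0)) return("eps must be non-negative")
  if (anyDuplicated(paste(object@i, object@j, object@frameTag)))
    return("duplicate contact pairs within a frame tag")
  if (!all(object@frameTag %in% c("N", "Nprime", "shared", "untagged")))
    return("frameTag must be one of N, Nprime, shared, untagged")
  TRUE
})

#' Dual-frame AFF topology
#'
#' Index bookkeeping for an alternate-frame-folding construct: a duplicated
#' segment appended N-terminally to the full-length chain through a linker,
#' creating two overlapping folding frames (N = the original fold, N' = the
#' circular-permutant fold) that share the non-duplicated segment.
#'
#' @slot wtLength length of the parent chain (residues).
#' @slot dupRange inclusive 1-based interval (length 2) of the duplicated
#'   parent residues; `c(0L, -1L)` denotes an empty (degenerate) duplication.
#' @slot linkerLength number of linker residues.
#' @slot totalLength construct length =
#'   `wtLength + |dupRange| + linkerLength`.
#' @slot frameN,frameNprime,shared integer vectors of construct residue
#'   indices making up each frame and their intersection.
#' @export
setClass("AFFTopology",
  representation(wtLength = "integer", dupRange = "integer",
                 linkerLength = "integer", totalLength = "integer",
                 frameN = "integer", frameNprime = "integer",
                 shared = "integer"))

setValidity("AFFTopology", function(object) {
  ndup <- max(0L, object@dupRange[2L] - object@dupRange[1L] + 1L)
  if (object@totalLength !=
      object@wtLength + ndup + object@linkerLength)
    return("totalLength must equal wtLength + |dupRange| + linkerLength")
  if (!setequal(intersect(object@frameN, object@frameNprime), object@shared))
    return("shared must equal the intersection of the two frames")
  dupCopy <- if (ndup > 0L) seq_len(ndup) else integer(0)
  if (length(intersect(dupCopy, object@frameN)))
    return("the duplicated copy and the original occupy disjoint indices")
  TRUE
})

#' Dual-frame native-centric (Go-type) AFF model
#'
#' The full energy model of an AFF construct: construct-length bead structure,
#' the union contact map over the N frame, N' frame and shared segment,
#' bonded terms (harmonic bonds and angles, periodic dihedrals), excluded
#' volume between all non-native, non-local pairs (which is what makes the
#' two frames fold mutually exclusively), reference folded conformations for
#' both frames, any applied delete-attractive mutations, and any ligand bias.
#'
#' @slot topology an [AFFTopology-class].
#' @slot beads a [BeadStructure-class] of construct length (N-fold reference
#'   geometry).
#' @slot contactMap a [ContactMap-class] (union of frames).
#' @slot bonds,angles,dihedrals numeric parameter matrices: bonds are
#'   (i, j, r0); angles (i, j, k, theta0); dihedrals (i, j, k, l, phi0).
#' @slot kb,ka,kd1,kd3 bonded force constants (energy / Angstrom^2,
#'   energy / rad^2, energy, energy).
#' @slot evSigma,evEps excluded-volume diameter (Angstrom) and prefactor.
#' @slot refN,refNprime full-construct reference conformations with frame N
#'   (resp. N') folded; RMSD progress coordinates are measured against these
#'   over the frame residues only.
#' @slot mutEps per-contact original well depths of delete-attractive
#'   mutated pairs (zero for live contacts); mutated pairs keep only the
#'   repulsive core of their 12-10 well (zeroed at `r0`), so attraction is
#'   removed while excluded volume is retained.
#' @slot mutations character vector of applied mutation labels.
#' @slot ligandBias list describing an applied ligand bias (empty if apo).
#' @slot units `"real"` (kcal/mol, Angstrom) or `"reduced"` (kT = 1).
#' @export
setClass("AFFModel",
  representation(topology = "AFFTopology", beads = "BeadStructure",
                 contactMap = "ContactMap",
                 bonds = "matrix", angles = "matrix", dihedrals = "matrix",
                 kb = "numeric", ka = "numeric",
                 kd1 = "numeric", kd3 = "numeric",
                 evSigma = "numeric", evEps = "numeric",
                 refN = "matrix", refNprime = "matrix",
                 mutEps = "numeric",
                 mutations = "character", ligandBias = "list",
                 units = "character"))

setValidity("AFFModel", function(object) {
  n <- nrow(object@beads@coords)
  cm <- object@contactMap
  if (length(cm@i) && (max(cm@j) > n || min(cm@i) < 1L))
    return("contact indices outside the construct")
  if (length(cm@i) && any(cm@r0 < object@evSigma & cm@eps > 0))
    return("contact with r0 below the excluded-volume diameter is unrealizable")
  if (nrow(object@bonds) && max(object@bonds[, 1:2]) > n)
    return("bond indices outside the construct")
  sh <- object@topology@shared
  bad <- cm@frameTag == "shared" & !(cm@i %in% sh & cm@j %in% sh)
  if (any(bad))
    return("shared-tagged contacts must lie entirely within the shared segment")
  if (!object@units %in% c("real", "reduced"))
    return("units must be 'real' or 'reduced'")
  if (length(object@mutEps) != length(cm@i))
    return("mutEps must parallel the contact map")
  if (any(object@mutEps > 0 & cm@eps > 0))
    return("a pair cannot be both live and mutated")
  TRUE
})

#' Weighted-ensemble run archive
#'
#' Per-iteration records of a WE run: walker weights, progress coordinates,
#' history labels, lineage pointers, recycling events and post-resampling
#' weight totals.  The archive is the input to all rate, stability, surface
#' and transition-path analyses.
#'
#' Each element of `iterations` is a list with elements `weight`, `pcoord`
#' (walkers x progress-dim matrix), `label` (character; `NA` = not yet in any
#' state), `parent` (index of each walker's pre-resampling ancestor in the
#' previous iteration; 0 in iteration 1), `parentRecycled` (logical: the
#' lineage was restarted from the initial state between the parent and this
#' walker), `recycled` (logical: this walker reached the target and was
#' recycled this iteration), `coords` (list of end configurations, present
#' when `storeCoords = TRUE`), `binCount` (walkers per occupied bin).
#'
#' @slot mode `"steady-state"` or `"equilibrium"`.
#' @slot config the WE configuration list used for the run (see [weConfig()]).
#' @slot iterations list of per-iteration records (see Details).
#' @slot sumWeight numeric; total weight after resampling, per iteration.
#' @slot flux numeric; recycled weight per iteration.
#' @slot tau segment length (time unit of the propagator).
#' @export
setClass("WEArchive",
  representation(mode = "character", config = "list", iterations = "list",
                 sumWeight = "numeric", flux = "numeric", tau = "numeric"))

setValidity("WEArchive", function(object) {
  if (!object@mode %in% c("steady-state", "equilibrium"))
    return("mode must be 'steady-state' or 'equilibrium'")
  if (length(object@flux) != length(object@iterations))
    return("flux must have one entry per iteration")
  if (any(object@flux < 0)) return("recycled flux must be non-negative")
  TRUE
})

#' Rectangular state definition on the progress coordinate
#'
#' A (possibly half-open) box in progress-coordinate space.  States used
#' together (e.g. initial and target of a steady-state run) must be disjoint.
#'
#' @slot id state identifier (e.g. `"N"`, `"Nprime"`, `"folded"`).
#' @slot lo,hi numeric vectors (length = progress dimension) of lower and
#'   upper bounds; use `-Inf`/`Inf` for unbounded sides.  Closed on both
#'   bounds, so the boundary belongs to the state.
#' @export
setClass("StateDefinition",
  representation(id = "character", lo = "numeric", hi = "numeric"))

setValidity("StateDefinition", function(object) {
  if (length(object@lo) != length(object@hi))
    return("lo and hi must have equal length")
  if (any(object@lo > object@hi)) return("state region is empty")
  TRUE
})

#' Rate-constant estimate from steady-state WE (k = f / p)
#'
#' @slot k rate constant, per time unit.
#' @slot f probability flux into the target per unit time.
#' @slot p time-averaged weight fraction carrying the initial-state history
#'   label (among labelled weight).
#' @slot sem standard error of `k` across independent runs (`NA` for a single
#'   run).
#' @slot nRuns number of independent archives combined.
#' @slot burnIn burn-in fraction discarded.
#' @slot nEvents total number of recycling events after burn-in.
#' @slot totalTime aggregate simulated time across all walkers (for
#'   efficiency accounting).
#' @export
setClass("RateEstimate",
  representation(k = "numeric", f = "numeric", p = "numeric",
                 sem = "numeric", nRuns = "integer", burnIn = "numeric",
                 nEvents = "numeric", totalTime = "numeric"))

setValidity("RateEstimate", function(object) {
  if (!identical(object@k, object@f / object@p))
    return("k must equal f / p exactly as stored")
  if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
  if (object@f < 0) return("f must be non-negative")
  TRUE
})

#' Folding-stability estimate
#'
#' @slot dG folding free energy `-kT ln(P_folded / P_unfolded)` (energy
#'   unit).
#' @slot pFolded,pUnfolded weight fractions of the two states.
#' @slot kT thermal energy used for the conversion.
#' @slot sem standard error of `dG` across independent runs (`NA` for one).
#' @slot nRuns number of archives combined.
#' @export
setClass("StabilityEstimate",
  representation(dG = "numeric", pFolded = "numeric", pUnfolded = "numeric",
                 kT = "numeric", sem = "numeric", nRuns = "integer"))

setValidity("StabilityEstimate", function(object) {
  if (!identical(object@dG,
                 -object@kT * log(object@pFolded / object@pUnfolded)))
    return("dG must equal -kT log(pFolded/pUnfolded) exactly as stored")
  TRUE
})

#' Probability / free-energy field over the progress coordinate
#'
#' Normalized probability mass per grid cell and the corresponding free
#' energy `G = -kT ln P` (defined only where `P > 0`).
#'
#' @slot breaks list of per-dimension bin edge vectors.
#' @slot mids list of per-dimension bin midpoints.
#' @slot P array of probability mass (sums to 1).
#' @slot G array, `-kT ln P` (NA where `P = 0`).
#' @slot kT thermal energy used.
#' @slot ensembleTag `"equilibrium"` or `"TPE-steady-state"`.
#' @export
setClass("ProbabilityField",
  representation(breaks = "list", mids = "list", P = "array", G = "array",
                 kT = "numeric", ensembleTag = "character"))

setValidity("ProbabilityField", function(object) {
  if (abs(sum(object@P) - 1) > 1e-9) return("P must sum to 1 (within 1e-9)")
  if (any(object@P < 0)) return("P must be non-negative")
  mx <- which.max(object@P)
  if (!is.na(object@G[mx]) && which.min(replace(object@G, is.na(object@G),
                                                Inf)) != mx)
    return("argmin G must coincide with argmax P")
  TRUE
})
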