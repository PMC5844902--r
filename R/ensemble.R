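#' @include kinetics.R
NULL

.gridIndex <- function(P, breaks) {
  dims <- vapply(breaks, function(e) length(e) - 1L, integer(1))
  idx <- matrix(0L, nrow(P), length(breaks))
  for (d in seq_along(breaks))
    idx[, d] <- pmin(pmax(findInterval(P[, d], breaks[[d]]), 1L), dims[d])
  idx
}

.accumulateField <- function(pcoords, weights, breaks) {
  dims <- vapply(breaks, function(e) length(e) - 1L, integer(1))
  idx <- .gridIndex(pcoords, breaks)
  lin <- idx[, 1L]
  mult <- dims[1L]
  for (d in seq_along(dims)[-1L]) {
    lin <- lin + (idx[, d] - 1L) * mult
    mult <- mult * dims[d]
  }
  A <- numeric(prod(dims))
  agg <- rowsum(weights, lin)
  A[as.integer(rownames(agg))] <- agg
  array(A, dim = dims)
}

.makeField <- function(A, breaks, kT, tag) {
  P <- A / sum(A)
  G <- -kT * log(P)
  G[P == 0] <- NA_real_
  mids <- lapply(breaks, function(e) (e[-1L] + e[-length(e)]) / 2)
  new("ProbabilityField", breaks = breaks, mids = mids, P = P, G = G,
      kT = kT, ensembleTag = tag)
}

#' Free-energy surface over the progress coordinate
#'
#' Accumulates walker weights into grid cells (burn-in removed) and converts
#' to `G = -kT ln P`.  Multiple independent archives are pooled by averaging
#' their normalized probability fields.
#'
#' @param archives a [WEArchive-class] or list of them sharing coordinate
#'   definitions.
#' @param breaks list of per-dimension bin edge vectors (default: the
#'   archives' WE bin edges).
#' @param kT thermal energy for the free-energy conversion.
#' @param burnIn burn-in fraction (default: archive's configured value).
#' @return a [ProbabilityField-class] tagged `"equilibrium"`.
#' @export
freeEnergySurface <- function(archives, breaks = NULL, kT = 1,
                              burnIn = NULL) {
  if (is(archives, "WEArchive")) archives <- list(archives)
  if (!length(archives)) stop("empty pooled ensemble")
  if (is.null(breaks)) breaks <- archives[[1L]]@config$binEdges
  fields <- lapply(archives, function(a) {
    bi <- if (is.null(burnIn)) a@config$burnIn else burnIn
    nIter <- length(a@iterations)
    use <- seq.int(floor(bi * nIter) + 1L, nIter)
    Ps <- do.call(rbind, lapply(use, function(t) a@iterations[[t]]$pcoord))
    Ws <- unlist(lapply(use, function(t) a@iterations[[t]]$weight))
    A <- .accumulateField(Ps, Ws, breaks)
    if (sum(A) == 0) stop("empty pooled ensemble")
    A / sum(A)
  })
  .makeField(Reduce(`+`, fields) / length(fields), breaks, kT,
             "equilibrium")
}

#' Probability mass of a field inside a rectangular region
#'
#' @param field a [ProbabilityField-class].
#' @param state a [StateDefinition-class] over the same coordinates.
#' @return total probability mass of cells whose midpoints fall inside.
#' @export
fieldMass <- function(field, state) {
  grid <- as.matrix(expand.grid(field@mids))
  sum(field@P[inState(grid, state)])
}

#' Extract the transition path ensemble from a steady-state archive
#'
#' For every recycling event into the target, walks the stored lineage
#' backwards to the last frame inside the initial state; the transition path
#' is the frame sequence strictly after that frame through the first frame
#' inside the target (the arrival frame).  Unproductive excursions are
#' excluded by construction; the path carries the recycled walker's weight.
#'
#' @param archive a steady-state [WEArchive-class].
#' @param initial,target [StateDefinition-class]s (default: the archive's
#'   configured states).
#' @param burnIn discard events in the first fraction of iterations
#'   (default: the archive's configured value; use 0 to keep everything).
#' @return list of transition paths; each is a list with `iterations`
#'   (iteration index per frame), `pcoords` (frames x dim), `coords` (list
#'   of configurations if the archive stored them), `weight`, `duration`
#'   (frames x tau).
#' @export
extractTPE <- function(archive, initial = NULL, target = NULL,
                       burnIn = NULL) {
  if (is.null(initial)) initial <- archive@config$initial
  if (is.null(target)) target <- archive@config$target
  if (is.null(burnIn)) burnIn <- archive@config$burnIn
  nIter <- length(archive@iterations)
  first <- floor(burnIn * nIter) + 1L
  paths <- list()
  for (t in seq.int(first, nIter)) {
    it <- archive@iterations[[t]]
    for (w in which(it$recycled)) {
      pw <- it$weight[w]
      revIters <- integer(0); revIdx <- integer(0)
      tt <- t; cur <- w
      repeat {
        rec <- archive@iterations[[tt]]
        if (cur < 1L || cur > length(rec$weight))
          stop("corrupt archive: broken lineage at iteration ", tt)
        if (inState(rec$pcoord[cur, , drop = FALSE], initial)[1L]) break
        revIters <- c(revIters, tt); revIdx <- c(revIdx, cur)
        if (rec$parentRecycled[cur] || rec$parent[cur] == 0L || tt == 1L)
          break
        cur <- rec$parent[cur]
        tt <- tt - 1L
      }
      ord <- rev(seq_along(revIters))
      iters <- revIters[ord]; idx <- revIdx[ord]
      if (!length(iters)) next
      pc <- do.call(rbind, lapply(seq_along(iters), function(q)
        archive@iterations[[iters[q]]]$pcoord[idx[q], , drop = FALSE]))
      cc <- NULL
      if (!is.null(archive@iterations[[iters[1L]]]$coords))
        cc <- lapply(seq_along(iters), function(q)
          archive@iterations[[iters[q]]]$coords[[idx[q]]])
      paths[[length(paths) + 1L]] <-
        list(iterations = iters, pcoords = pc, coords = cc, weight = pw,
             origin = initial@id, destination = target@id,
             duration = length(iters) * archive@tau)
    }
  }
  paths
}

#' Probability field of a transition path ensemble
#'
#' Path frames enter the field weighted by their path's weight, uniform
#' across a path's frames (steady-state probability density over productive
#' segments).
#'
#' @param paths list of transition paths from [extractTPE()].
#' @param breaks list of per-dimension bin edge vectors.
#' @param kT thermal energy.
#' @return a [ProbabilityField-class] tagged `"TPE-steady-state"`.
#' @export
tpeField <- function(paths, breaks, kT = 1) {
  if (!length(paths)) stop("empty transition path ensemble")
  Ps <- do.call(rbind, lapply(paths, `[[`, "pcoords"))
  Ws <- unlist(lapply(paths, function(p)
    rep(p$weight, nrow(p$pcoords))))
  .makeField(.accumulateField(Ps, Ws, breaks), breaks, kT,
             "TPE-steady-state")
}

#' Frames and weights of a transition path ensemble
#'
#' With `weighting = "path"` frames carry their path's steady-state weight
#' (the probability-density convention of [tpeField()]).  Recycled path
#' weights span many orders of magnitude, so at small path counts that
#' estimator is dominated by one or two heavy paths; `weighting =
#' "uniform"` gives every path equal weight (frames within a path share
#' it), the pathway-diversity convention that keeps per-residue contact
#' scores statistically meaningful on modest ensembles.
#'
#' @param paths list from [extractTPE()] (archives must have stored
#'   coordinates).
#' @param weighting `"path"` or `"uniform"` (see Details).
#' @return list with `frames` (configurations) and `weights`.
#' @export
tpeFrames <- function(paths, weighting = c("path", "uniform")) {
  weighting <- match.arg(weighting)
  if (!length(paths)) stop("empty transition path ensemble")
  if (is.null(paths[[1L]]$coords))
    stop("archive did not store coordinates (set storeCoords = TRUE)")
  list(frames = do.call(c, lapply(paths, `[[`, "coords")),
       weights = unlist(lapply(paths, function(p) {
         w <- if (weighting == "path") p$weight else 1 / length(p$coords)
         rep(w, length(p$coords))
       })))
}

#' Frames and weights of a state ensemble from an archive
#'
#' @param archive a [WEArchive-class] run with `storeCoords = TRUE`.
#' @param state keep only frames inside this [StateDefinition-class]
#'   (`NULL` = all frames).
#' @param burnIn burn-in fraction.
#' @return list with `frames` and `weights`.
#' @export
ensembleFrames <- function(archive, state = NULL, burnIn = NULL) {
  if (is.null(burnIn)) burnIn <- archive@config$burnIn
  nIter <- length(archive@iterations)
  use <- seq.int(floor(burnIn * nIter) + 1L, nIter)
  frames <- list(); weights <- numeric(0)
  for (t in use) {
    it <- archive@iterations[[t]]
    if (is.null(it$coords))
      stop("archive did not store coordinates (set storeCoords = TRUE)")
    keep <- if (is.null(state)) rep(TRUE, length(it$weight))
            else inState(it$pcoord, state)
    frames <- c(frames, it$coords[keep])
    weights <- c(weights, it$weight[keep])
  }
  list(frames = frames, weights = weights)
}

#' Per-residue contact scores of an ensemble
#'
#' A native contact is "formed" in a frame when its pair distance is at most
#' `formationFactor * r0`; a residue's contact score is the ensemble-
#' weighted mean number of formed native contacts it participates in.
#'
#' @param frames list of coordinate matrices.
#' @param weights positive frame weights.
#' @param map a [ContactMap-class]; pass a frame-restricted map to score one
#'   frame's contacts only.
#' @param nResidues number of residues (rows of each frame).
#' @param formationFactor formation criterion (default 1.2, config-exposed).
#' @return numeric vector of per-residue scores.
#' @export
contactScore <- function(frames, weights, map, nResidues,
                         formationFactor = 1.2) {
  stopifnot(length(frames) == length(weights), all(weights > 0))
  if (length(map@i) && max(map@j) > nResidues)
    stop("contact map references residues absent from the frames")
  counts <- cpp_contact_counts(frames, map@i, map@j, map@r0,
                               formationFactor, nResidues)
  as.numeric(crossprod(counts, weights) / sum(weights))
}

#' Restrict a contact map to given frame tags
#'
#' @param map a [ContactMap-class].
#' @param tags frame tags to keep (e.g. `c("N", "shared")` for the N frame).
#' @return the restricted [ContactMap-class].
#' @export
filterContacts <- function(map, tags) {
  keep <- map@frameTag %in% tags
  methods::initialize(map, i = map@i[keep], j = map@j[keep],
                      r0 = map@r0[keep], eps = map@eps[keep],
                      frameTag = map@frameTag[keep])
}

#' Contact-score table across ensembles
#'
#' Builds the per-residue score table over the four canonical ensembles of
#' the design screen — the two ground states and the two directional
#' transition path ensembles — with cross-simulation s.e.m. when several
#' independent (frames, weights) sets are supplied per ensemble.
#'
#' @param ensembles named list; each element is a list of per-simulation
#'   lists with `frames` and `weights` (one per independent run).
#' @param maps named list of [ContactMap-class]s, one per ensemble entry
#'   (the frame-appropriate restriction; see [filterContacts()]).
#' @param nResidues construct length.
#' @param formationFactor formation criterion.
#' @return data.frame with columns `residue`, then `score_<name>` and
#'   `sem_<name>` per ensemble.
#' @export
contactScoreTable <- function(ensembles, maps, nResidues,
                              formationFactor = 1.2) {
  out <- data.frame(residue = seq_len(nResidues))
  for (nm in names(ensembles)) {
    perSim <- vapply(ensembles[[nm]], function(e)
      contactScore(e$frames, e$weights, maps[[nm]], nResidues,
                   formationFactor), numeric(nResidues))
    perSim <- matrix(perSim, nrow = nResidues)
    out[[paste0("score_", nm)]] <- rowMeans(perSim)
    out[[paste0("sem_", nm)]] <- if (ncol(perSim) >= 2L)
      apply(perSim, 1L, stats::sd) / sqrt(ncol(perSim)) else NA_real_
  }
  out
}

#' Rank candidate residues for rate-enhancing mutation
#'
#' Implements the design screen: residues are ordered by how much lower
#' their contact score is in the transition path ensemble than in the
#' relevant ground state (`diff_fwd = score_N - score_TPE_fwd`,
#' `diff_rev = score_Nprime - score_TPE_rev`), combined across directions as
#' the sum of the two max-normalized differences.  Residues in (or supplied
#' as adjacent to) the binding site are flagged and excluded from the
#' candidate list, as are residues whose mutant stability violates the
#' floor.  The negative control is the buried interface residue (relative
#' contact degree at least the median over the interface set) with the
#' smallest summed magnitude of the two normalized score differences (so
#' per-direction changes of opposite sign cannot masquerade as "no
#' change"), ties broken by residue index.
#'
#' @param scores data.frame from [contactScoreTable()] with ensembles named
#'   `N`, `Nprime`, `TPE_fwd`, `TPE_rev`.
#' @param map the construct [ContactMap-class] (for contact degrees).
#' @param interfaceResidues residue indices of the packing interface set
#'   over which the negative control is selected.
#' @param bindingSite residue indices in/adjacent to the ligand-binding
#'   site (excluded from candidacy).
#' @param stability optional named numeric of mutant folding free energies
#'   (names = residue indices).
#' @param stabilityFloor exclude residues whose mutant `dG_fold` exceeds
#'   this value (default -2, the minimum stability margin retained).
#' @return data.frame of ranked candidates (flags included), with the
#'   negative-control residue in attribute `negativeControl`.
#' @export
rankCandidates <- function(scores, map, interfaceResidues,
                           bindingSite = integer(0), stability = NULL,
                           stabilityFloor = -2) {
  if (!nrow(scores)) stop("empty score table")
  need <- c("score_N", "score_Nprime", "score_TPE_fwd", "score_TPE_rev")
  stopifnot(all(need %in% names(scores)))
  df <- scores
  df$diff_fwd <- df$score_N - df$score_TPE_fwd
  df$diff_rev <- df$score_Nprime - df$score_TPE_rev
  nz <- function(x) if (max(abs(x), na.rm = TRUE) > 0)
    x / max(abs(x), na.rm = TRUE) else x
  df$combined <- nz(df$diff_fwd) + nz(df$diff_rev)
  # for the negative control, opposite-sign per-direction changes must not
  # cancel: the "no change" criterion is the summed magnitude
  df$absChange <- abs(nz(df$diff_fwd)) + abs(nz(df$diff_rev))
  df$flag_binding_site <- df$residue %in% bindingSite
  df$flag_unstable <- FALSE
  if (!is.null(stability)) {
    hit <- match(df$residue, as.integer(names(stability)))
    df$flag_unstable <- !is.na(hit) & stability[hit] > stabilityFloor
  }
  degree <- tabulate(c(map@i, map@j), nbins = nrow(df))
  iface <- df$residue %in% interfaceResidues
  buried <- iface & degree >= stats::median(degree[iface])
  cand <- df[!df$flag_binding_site & !df$flag_unstable, , drop = FALSE]
  cand <- cand[order(-cand$combined, cand$residue), , drop = FALSE]
  negPool <- df[buried, , drop = FALSE]
  neg <- negPool$residue[order(negPool$absChange, negPool$residue)][1L]
  structure(cand, negativeControl = neg)
}

setMethod("show", "ProbabilityField", function(object) {
  cat(sprintf("ProbabilityField (%s): %s grid, kT = %g\n",
              object@ensembleTag,
              paste(dim(object@P), collapse = " x "), object@kT))
})

#' Export a probability field as TSV
#'
#' @param field a [ProbabilityField-class].
#' @param file output path.
#' @return the path, invisibly.
#' @export
writeField <- function(field, file) {
  grid <- expand.grid(field@mids)
  names(grid) <- paste0("coord", seq_along(field@mids))
  grid$P <- as.vector(field@P)
  grid$G <- as.vector(field@G)
  utils::write.table(grid, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
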