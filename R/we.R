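#' @include dynamics.R
NULL

#' Define a rectangular state on the progress coordinate
#'
#' @param id state identifier.
#' @param lo,hi numeric bounds per progress dimension (closed; use
#'   `-Inf`/`Inf` for unbounded sides).
#' @return a [StateDefinition-class].
#' @export
stateDefinition <- function(id, lo, hi) {
  new("StateDefinition", id = id, lo = as.numeric(lo), hi = as.numeric(hi))
}

setMethod("show", "StateDefinition", function(object) {
  cat(sprintf("State '%s': [%s] .. [%s]\n", object@id,
              paste(signif(object@lo, 4), collapse = ", "),
              paste(signif(object@hi, 4), collapse = ", ")))
})

#' Test progress coordinates for state membership
#'
#' @param pcoords numeric matrix (walkers x progress dimension) or vector.
#' @param state a [StateDefinition-class].
#' @return logical vector.
#' @export
inState <- function(pcoords, state) {
  P <- if (is.matrix(pcoords)) pcoords else matrix(pcoords, ncol = length(state@lo))
  ok <- rep(TRUE, nrow(P))
  for (d in seq_along(state@lo))
    ok <- ok & P[, d] >= state@lo[d] & P[, d] <= state@hi[d]
  ok
}

# walkers x d progress-coordinate matrix from a list of configurations
.pcoordMat <- function(xs, pfun, d) {
  v <- vapply(xs, pfun, numeric(d))
  if (d == 1L) matrix(v, ncol = 1L) else t(v)
}

.statesDisjoint <- function(states) {
  if (length(states) < 2L) return(TRUE)
  for (a in seq_len(length(states) - 1L))
    for (b in (a + 1L):length(states)) {
      sa <- states[[a]]; sb <- states[[b]]
      if (all(pmax(sa@lo, sb@lo) <= pmin(sa@hi, sb@hi))) return(FALSE)
    }
  TRUE
}

#' Weighted-ensemble run configuration
#'
#' @param mode `"steady-state"` (recycling into the initial state) or
#'   `"equilibrium"` (no recycling).
#' @param binEdges list with one sorted break vector per progress dimension.
#'   Bins are half-open `[low, high)`; the outermost bins absorb over- and
#'   underflow.
#' @param walkersPerBin target trajectories per occupied bin (default 4).
#' @param nIterations number of WE iterations of length `tau`.
#' @param initial,target [StateDefinition-class]s of the initial and target
#'   states (target required in steady-state mode; both optional in
#'   equilibrium mode, where they only drive history labels).
#' @param seed RNG seed; together with the configuration and model it fully
#'   determines the run.
#' @param storeCoords keep end-of-segment configurations in the archive
#'   (needed for contact-score analysis; off by default to save memory).
#' @param initialWalkers optional warm start: a list with `coords` (list of
#'   configurations), `weight` and optionally `label`, e.g. the
#'   `finalState` stored in a previous archive's configuration; weights are
#'   renormalized.  Overrides the initial-state sampler.
#' @param burnIn default burn-in fraction recorded for downstream analysis
#'   (default 0.1, i.e. analyses use the latter 90 percent).
#' @return a classed configuration list.
#' @export
weConfig <- function(mode = c("steady-state", "equilibrium"), binEdges,
                     walkersPerBin = 4L, nIterations = 100L,
                     initial = NULL, target = NULL, seed = 1L,
                     storeCoords = FALSE, burnIn = 0.1,
                     initialWalkers = NULL) {
  mode <- match.arg(mode)
  if (!is.list(binEdges)) binEdges <- list(binEdges)
  stopifnot(walkersPerBin >= 1L, nIterations >= 1L)
  if (mode == "steady-state" && (is.null(initial) || is.null(target)))
    stop("steady-state mode requires defined initial and target states")
  states <- Filter(Negate(is.null), list(initial = initial, target = target))
  if (!.statesDisjoint(states))
    stop("state definitions overlap")
  structure(list(mode = mode, binEdges = binEdges,
                 walkersPerBin = as.integer(walkersPerBin),
                 nIterations = as.integer(nIterations),
                 initial = initial, target = target, seed = seed,
                 storeCoords = storeCoords, burnIn = burnIn,
                 initialWalkers = initialWalkers),
            class = "WEConfig")
}

#' Assign walkers to progress-coordinate bins
#'
#' Bins are half-open `[low, high)` per dimension; the outermost bins absorb
#' over- and underflow, so every finite coordinate maps to exactly one bin.
#' Walkers with non-finite coordinates are quarantined (bin `NA`) and
#' reported in the `quarantined` attribute.
#'
#' @param pcoords numeric matrix (walkers x dimensions) or vector.
#' @param binEdges list of sorted break vectors, one per dimension.
#' @return integer vector of linear bin indices, with attribute
#'   `quarantined` (indices of non-finite walkers).
#' @export
assignBins <- function(pcoords, binEdges) {
  if (!is.list(binEdges)) binEdges <- list(binEdges)
  P <- if (is.matrix(pcoords)) pcoords else matrix(pcoords, ncol = length(binEdges))
  stopifnot(ncol(P) == length(binEdges))
  bad <- !apply(P, 1L, function(r) all(is.finite(r)))
  lin <- rep(1L, nrow(P))
  mult <- 1L
  for (d in seq_along(binEdges)) {
    e <- binEdges[[d]]
    m <- length(e) - 1L
    i <- pmin(pmax(findInterval(P[, d], e), 1L), m)
    lin <- lin + (i - 1L) * mult
    mult <- mult * m
  }
  lin[bad] <- NA_integer_
  structure(lin, quarantined = which(bad))
}

#' Split/merge a bin's walkers to a target count
#'
#' Splitting repeatedly halves the highest-weight walker (each split divides
#' the parent's weight equally among its clones); merging repeatedly
#' combines the two lowest-weight walkers, the survivor drawn with
#' probability proportional to weight and absorbing both weights.  Total
#' weight is conserved and the expectation of any weight-linear observable
#' is preserved.
#'
#' @param weights positive weights of the walkers currently in the bin.
#' @param targetCount desired number of walkers (>= 1).
#' @return list with `origin` (index into the input walkers each output
#'   walker descends from) and `weight`.
#' @export
resampleBin <- function(weights, targetCount) {
  if (targetCount < 1L) stop("targetCount must be >= 1")
  n <- length(weights)
  if (n == 0L) stop("bin is empty")
  origin <- seq_len(n)
  w <- as.numeric(weights)
  while (length(w) < targetCount) {
    h <- which.max(w)
    w <- c(w, w[h] / 2)
    w[h] <- w[h] / 2
    origin <- c(origin, origin[h])
  }
  while (length(w) > targetCount) {
    o <- order(w)[1:2]
    keep <- if (stats::runif(1) < w[o[1L]] / (w[o[1L]] + w[o[2L]]))
      o[1L] else o[2L]
    drop <- setdiff(o, keep)
    w[keep] <- w[o[1L]] + w[o[2L]]
    w <- w[-drop]
    origin <- origin[-drop]
  }
  list(origin = origin, weight = w)
}

#' Update walker history labels
#'
#' A walker inside a state gets that state's label; outside every state the
#' label is inherited unchanged (through splits and merges the survivor's
#' label carries on).  Walkers that have never entered a state keep `NA`
#' ("unset") and are excluded from the `p_i` of the rate estimator until
#' first entry.
#'
#' @param labels character vector of current labels (`NA` = unset).
#' @param pcoords walkers x dimension matrix of progress coordinates.
#' @param states list of disjoint [StateDefinition-class]s.
#' @return updated character vector.
#' @export
updateHistoryLabels <- function(labels, pcoords, states) {
  if (!.statesDisjoint(states)) stop("state definitions overlap")
  for (s in states) {
    hit <- inState(pcoords, s)
    labels[hit] <- s@id
  }
  labels
}

#' Recycle walkers that reached the target state
#'
#' In steady-state mode every walker inside the target is terminated and
#' replaced by a fresh initial-state walker carrying the identical weight;
#' the summed replaced weight is the recycled flux of the iteration.  In
#' equilibrium mode this is the identity with zero flux.
#'
#' @param walkers list with elements `coords` (list), `weight`, `pcoord`
#'   (matrix), `label`.
#' @param target target [StateDefinition-class].
#' @param sampler function(n) returning a list of n initial configurations.
#' @param progressFun function(coords) returning the progress coordinate.
#' @param mode `"steady-state"` or `"equilibrium"`.
#' @param initialLabel label assigned to replacements (the initial state id).
#' @return list with updated `walkers`, `flux` and logical `recycled`.
#' @export
recycleWalkers <- function(walkers, target, sampler, progressFun,
                           mode = "steady-state", initialLabel = NA) {
  if (mode != "steady-state")
    return(list(walkers = walkers, flux = 0, recycled =
                  rep(FALSE, length(walkers$weight))))
  hit <- inState(walkers$pcoord, target)
  flux <- sum(walkers$weight[hit])
  if (any(hit)) {
    repl <- sampler(sum(hit))
    walkers$coords[hit] <- repl
    d <- ncol(walkers$pcoord)
    walkers$pcoord[hit, ] <- .pcoordMat(repl, progressFun, d)
    walkers$label[hit] <- initialLabel
  }
  list(walkers = walkers, flux = flux, recycled = hit)
}

#' Run a weighted-ensemble simulation
#'
#' Orchestrates binned splitting/merging at fixed `tau` intervals over the
#' propagator's dynamics, with steady-state recycling or equilibrium (no
#' recycling) weight management.  All randomness draws from R's RNG seeded
#' with `config$seed`, so a fixed (seed, configuration, model) triple
#' reproduces the archive exactly.
#'
#' @param propagator an object with [runSegment()], [computeProgress()],
#'   [progressDim()] and [initialConfigurations()] methods (see
#'   [goPropagator()], [makeDoubleWell()]).
#' @param config a [weConfig()].
#' @return a [WEArchive-class].
#' @examples
#' dw <- makeDoubleWell(barrier = 3)
#' cfg <- weConfig("equilibrium", binEdges = dw$binEdges,
#'                 nIterations = 50, seed = 7,
#'                 initial = dw$stateA, target = dw$stateB)
#' arc <- runWE(dw$propagator, cfg)
#' range(weightTotals(arc) - 1)
#' @export
runWE <- function(propagator, config) {
  set.seed(config$seed)
  d <- progressDim(propagator)
  states <- Filter(Negate(is.null), list(config$initial, config$target))
  nIter <- config$nIterations
  pfun <- function(x) computeProgress(propagator, x)
  if (!is.null(config$initialWalkers)) {
    # warm start from a pre-equilibrated walker set (e.g. the final state
    # of an equilibrium run), the standard way to seed steady-state runs
    iw <- config$initialWalkers
    coords <- iw$coords
    weight <- iw$weight / sum(iw$weight)
    label <- if (!is.null(iw$label)) iw$label
             else rep(NA_character_, length(weight))
  } else {
    n0 <- config$walkersPerBin
    coords <- initialConfigurations(propagator, n0)
    weight <- rep(1 / n0, n0)
    label <- rep(NA_character_, n0)
  }
  P <- .pcoordMat(coords, pfun, d)
  label <- updateHistoryLabels(label, P, states)
  originPrev <- rep(0L, length(weight))
  recycledPrev <- rep(FALSE, length(weight))
  iterations <- vector("list", nIter)
  sumWeight <- flux <- numeric(nIter)

  for (t in seq_len(nIter)) {
    ends <- lapply(coords, function(x) runSegment(propagator, x)$end)
    P <- .pcoordMat(ends, pfun, d)
    label <- updateHistoryLabels(label, P, states)
    rec <- list(weight = weight, pcoord = P, label = label,
                parent = originPrev, parentRecycled = recycledPrev)
    if (config$storeCoords) rec$coords <- ends

    walkers <- list(coords = ends, weight = weight, pcoord = P,
                    label = label)
    rc <- recycleWalkers(walkers, config$target,
                         function(n) initialConfigurations(propagator, n),
                         pfun, mode = config$mode,
                         initialLabel = if (is.null(config$initial)) NA
                                        else config$initial@id)
    rec$recycled <- rc$recycled
    rec$recycledWeight <- weight * as.numeric(rc$recycled)
    flux[t] <- rc$flux
    ends <- rc$walkers$coords
    P <- rc$walkers$pcoord
    label <- rc$walkers$label

    bins <- assignBins(P, config$binEdges)
    if (length(attr(bins, "quarantined")))
      stop("non-finite progress coordinate at iteration ", t,
           " (walkers ", paste(attr(bins, "quarantined"), collapse = ","),
           ")")
    newOrigin <- integer(0)
    newWeight <- numeric(0)
    for (b in sort(unique(bins))) {
      members <- which(bins == b)
      rs <- resampleBin(weight[members], config$walkersPerBin)
      newOrigin <- c(newOrigin, members[rs$origin])
      newWeight <- c(newWeight, rs$weight)
    }
    rec$binCount <- as.integer(table(bins))
    iterations[[t]] <- rec

    coords <- ends[newOrigin]
    weight <- newWeight
    label <- label[newOrigin]
    originPrev <- newOrigin
    recycledPrev <- rc$recycled[newOrigin]
    sumWeight[t] <- sum(weight)
  }

  new("WEArchive", mode = config$mode,
      config = c(unclass(config),
                 list(tau = .propTau(propagator),
                      finalState = list(coords = coords, weight = weight,
                                        label = label))),
      iterations = iterations, sumWeight = sumWeight, flux = flux,
      tau = .propTau(propagator))
}

# segment length of a propagator (time units)
.propTau <- function(propagator) {
  cf <- propagator@config
  cf$tau
}

#' @rdname nIterations
#' @export
setMethod("nIterations", "WEArchive", function(x) length(x@iterations))

#' @rdname recycledFlux
#' @export
setMethod("recycledFlux", "WEArchive", function(x) x@flux)

#' @rdname weightTotals
#' @export
setMethod("weightTotals", "WEArchive", function(x) x@sumWeight)

setMethod("show", "WEArchive", function(object) {
  cat(sprintf("WEArchive: %s mode, %d iterations (tau = %g)\n",
              object@mode, length(object@iterations), object@tau))
  cat(sprintf("  max |sum(w) - 1| = %.2e; total recycled flux = %.4g\n",
              max(abs(object@sumWeight - 1)), sum(object@flux)))
})

#' Fraction of walker weight with unset history label, per iteration
#'
#' Reported so users can confirm the unset fraction decays as trajectories
#' first reach a state.
#'
#' @param archive a [WEArchive-class].
#' @return numeric vector.
#' @export
unsetLabelFraction <- function(archive) {
  vapply(archive@iterations, function(it)
    sum(it$weight[is.na(it$label)]) / sum(it$weight), numeric(1))
}
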