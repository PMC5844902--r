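#' @include we.R
NULL

# weighted histogram of an archive's progress coordinate along one axis,
# over the archive's own bin edges, burn-in removed
.archiveHistogram <- function(archive, axis = 1L, burnIn = NULL,
                              edges = NULL) {
  if (is.null(burnIn)) burnIn <- archive@config$burnIn
  if (is.null(edges)) edges <- archive@config$binEdges[[axis]]
  nIter <- length(archive@iterations)
  use <- seq.int(floor(burnIn * nIter) + 1L, nIter)
  m <- length(edges) - 1L
  P <- numeric(m)
  for (t in use) {
    it <- archive@iterations[[t]]
    b <- pmin(pmax(findInterval(it$pcoord[, axis], edges), 1L), m)
    P <- P + unname(vapply(seq_len(m), function(k)
      sum(it$weight[b == k]), numeric(1)))
  }
  P / sum(P)
}

# time-averaged weight inside a state region (burn-in removed)
.stateWeight <- function(archive, state, burnIn = NULL) {
  if (is.null(burnIn)) burnIn <- archive@config$burnIn
  nIter <- length(archive@iterations)
  use <- seq.int(floor(burnIn * nIter) + 1L, nIter)
  mean(vapply(use, function(t) {
    it <- archive@iterations[[t]]
    sum(it$weight[inState(it$pcoord, state)])
  }, numeric(1)))
}

#' Define two states from an equilibrium histogram
#'
#' Applies the mode rule: the boundary of each state is placed at the
#' position of the probability-distribution maximum along the progress
#' coordinate.  The two highest local maxima become the state boundaries;
#' boundary ties resolve toward the basin (the boundary bin belongs to the
#' state), making the regions closed and disjoint.
#'
#' @param archive an equilibrium [WEArchive-class] with a converged
#'   histogram.
#' @param axis progress-coordinate dimension to use (default 1).
#' @param ids identifiers for the (low-coordinate, high-coordinate) states.
#' @param burnIn burn-in fraction (default: the archive's configured value).
#' @param minModeFraction a local maximum must carry at least this fraction
#'   of the tallest bin's mass to count as a basin (noise floor).
#' @return list of two [StateDefinition-class]s.
#' @export
defineStates <- function(archive, axis = 1L, ids = c("A", "B"),
                         burnIn = NULL, minModeFraction = 0.05) {
  edges <- archive@config$binEdges[[axis]]
  P <- .archiveHistogram(archive, axis, burnIn, edges)
  defineStatesFromHistogram(P, edges, ids, minModeFraction)
}

#' @describeIn defineStates apply the mode rule to an explicit histogram
#'   (`P` = probability mass per bin over `edges`).
#' @param P numeric vector of per-bin probability mass.
#' @param edges bin edge vector (length `length(P) + 1`).
#' @export
defineStatesFromHistogram <- function(P, edges, ids = c("A", "B"),
                                      minModeFraction = 0.05) {
  m <- length(P)
  left <- c(-Inf, P[-m])
  right <- c(P[-1L], -Inf)
  modes <- which(P > left & P > right & P >= minModeFraction * max(P))
  # the outermost bins absorb over/underflow by the binning convention and
  # cannot be basins
  modes <- setdiff(modes, c(1L, m))
  if (length(modes) >= 2L) {
    top2 <- sort(modes[order(P[modes], decreasing = TRUE)[1:2]])
    # two usable basins must be separated by a genuine dip: without one
    # (flat or diffusive distributions) there is nothing metastable
    valley <- min(P[top2[1L]:top2[2L]])
    if (valley > 0.6 * min(P[top2])) modes <- modes[0]
  }
  if (length(modes) < 2L)
    stop("cannot define two states: probability distribution has ",
         length(modes), " usable mode(s)")
  top2 <- modes[order(P[modes], decreasing = TRUE)[1:2]]
  lowBin <- min(top2); highBin <- max(top2)
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  list(stateDefinition(ids[1L], -Inf, mids[lowBin]),
       stateDefinition(ids[2L], mids[highBin], Inf))
}

#' Estimate a rate constant from steady-state WE archives (k = f / p)
#'
#' `f` is the recycled probability flux into the target per unit time,
#' averaged after burn-in; `p` is the time-averaged weight fraction carrying
#' the initial-state history label among labelled weight (probability-
#' weighted, consistent with WE weight semantics; unset labels are excluded
#' from numerator and denominator).  With two or more independent archives
#' the s.e.m. of `k` across archives is reported.
#'
#' @param archives a steady-state [WEArchive-class] or list of independent
#'   ones (same states and configuration).
#' @param burnIn burn-in fraction (default: the archives' configured value).
#' @return a [RateEstimate-class]; rate in 1 / (propagator time unit).
#' @export
estimateRate <- function(archives, burnIn = NULL) {
  if (is(archives, "WEArchive")) archives <- list(archives)
  per <- lapply(archives, function(a) {
    if (a@mode != "steady-state")
      stop("rate estimation needs steady-state archives")
    if (is.null(burnIn)) burnIn <- a@config$burnIn
    nIter <- length(a@iterations)
    use <- seq.int(floor(burnIn * nIter) + 1L, nIter)
    iid <- a@config$initial@id
    f <- mean(a@flux[use]) / a@tau
    p <- mean(vapply(use, function(t) {
      it <- a@iterations[[t]]
      lab <- sum(it$weight[!is.na(it$label)])
      if (lab == 0) return(NA_real_)
      sum(it$weight[!is.na(it$label) & it$label == iid]) / lab
    }, numeric(1)), na.rm = TRUE)
    ev <- sum(vapply(use, function(t)
      sum(a@iterations[[t]]$recycled), numeric(1)))
    cost <- sum(vapply(a@iterations, function(it)
      length(it$weight), numeric(1))) * a@tau
    c(f = f, p = p, k = f / p, ev = ev, cost = cost)
  })
  per <- do.call(rbind, per)
  f <- mean(per[, "f"]); p <- mean(per[, "p"])
  nEvents <- sum(per[, "ev"])
  if (nEvents == 0)
    warning("zero recycling events after burn-in; ",
            "rate is an upper bound (one event over the simulated time)")
  if (f == 0) f <- 1 / sum(per[, "cost"]) # upper bound: < one event overall
  sem <- if (nrow(per) >= 2L)
    stats::sd(per[, "k"]) / sqrt(nrow(per)) else NA_real_
  new("RateEstimate", k = f / p, f = f, p = p, sem = sem,
      nRuns = nrow(per), burnIn = if (is.null(burnIn)) 0.1 else burnIn,
      nEvents = nEvents, totalTime = sum(per[, "cost"]))
}

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf(
    "RateEstimate: k = %.4g (f = %.4g, p = %.4g)%s; %d run(s), %g events\n",
    object@k, object@f, object@p,
    if (is.na(object@sem)) "" else sprintf(" +- %.2g s.e.m.", object@sem),
    object@nRuns, object@nEvents))
})

#' Estimate folding stability from WE simulation
#'
#' From one or more equilibrium archives: `dG = -kT ln(P_folded /
#' P_unfolded)` with the two probabilities read off the time-averaged weight
#' in the state regions.  Alternatively, opposing steady-state simulations
#' (folding and unfolding) can be combined: the equilibrium population ratio
#' equals the ratio of the two directional rate constants, so
#' `dG = -kT ln(k_fold / k_unfold)`.
#'
#' @param archives an equilibrium [WEArchive-class] or list of them.
#' @param folded,unfolded [StateDefinition-class]s of the two basins.
#' @param kT thermal energy (energy unit of the model).
#' @param burnIn burn-in fraction (default: archive's configured value).
#' @param method `"region"` reads the weight inside the two state regions;
#'   `"label"` uses the history-labelled weight fractions (every walker
#'   counts toward the state it visited last), the quantity whose ratio is
#'   exactly reproduced by the directional rate-constant ratio of
#'   [stabilityFromRates()].
#' @return a [StabilityEstimate-class].
#' @export
estimateStability <- function(archives, folded, unfolded, kT,
                              burnIn = NULL,
                              method = c("region", "label")) {
  method <- match.arg(method)
  if (is(archives, "WEArchive")) archives <- list(archives)
  wOf <- function(a, state) {
    if (method == "region") return(.stateWeight(a, state, burnIn))
    bi <- if (is.null(burnIn)) a@config$burnIn else burnIn
    nIter <- length(a@iterations)
    use <- seq.int(floor(bi * nIter) + 1L, nIter)
    mean(vapply(use, function(t) {
      it <- a@iterations[[t]]
      sum(it$weight[!is.na(it$label) & it$label == state@id])
    }, numeric(1)))
  }
  dGs <- vapply(archives, function(a) {
    pf <- wOf(a, folded)
    pu <- wOf(a, unfolded)
    if (pf == 0 || pu == 0)
      stop("undefined stability: a state has zero accumulated weight")
    -kT * log(pf / pu)
  }, numeric(1))
  pf <- mean(vapply(archives, wOf, numeric(1), state = folded))
  pu <- mean(vapply(archives, wOf, numeric(1), state = unfolded))
  sem <- if (length(dGs) >= 2L) stats::sd(dGs) / sqrt(length(dGs))
         else NA_real_
  new("StabilityEstimate", dG = -kT * log(pf / pu), pFolded = pf,
      pUnfolded = pu, kT = kT, sem = sem, nRuns = length(archives))
}

#' @describeIn estimateStability combine opposing steady-state rate
#'   estimates (folding and unfolding) into an equilibrium stability.
#' @param rateFold,rateUnfold [RateEstimate-class]s of the folding and
#'   unfolding directions.
#' @export
stabilityFromRates <- function(rateFold, rateUnfold, kT) {
  kf <- rateFold@k; ku <- rateUnfold@k
  pf <- kf / (kf + ku); pu <- ku / (kf + ku)
  sem <- if (!is.na(rateFold@sem) && !is.na(rateUnfold@sem))
    kT * sqrt((rateFold@sem / kf)^2 + (rateUnfold@sem / ku)^2)
  else NA_real_
  new("StabilityEstimate", dG = -kT * log(pf / pu), pFolded = pf,
      pUnfolded = pu, kT = kT, sem = sem,
      nRuns = rateFold@nRuns + rateUnfold@nRuns)
}

setMethod("show", "StabilityEstimate", function(object) {
  cat(sprintf(
    "StabilityEstimate: dG_fold = %.3f%s (P_f = %.4g, P_u = %.4g)\n",
    object@dG,
    if (is.na(object@sem)) "" else sprintf(" +- %.3f s.e.m.", object@sem),
    object@pFolded, object@pUnfolded))
})

#' Free-energy barrier reduction implied by a rate fold-change
#'
#' `ddG = RT ln(k_mut / k_WT)`; a fold-change above 1 means the barrier was
#' reduced by `ddG`.
#'
#' @param foldChange `k_mut / k_WT` (> 0).
#' @param temperature kelvin (default 293.15).
#' @param kT explicit thermal energy override (then `temperature` is
#'   ignored); use for reduced-unit models.
#' @return list with `foldChange`, `temperature`, `ddG` and `ddGRounded`
#'   (one decimal, as reported in summaries).
#' @examples
#' barrierReduction(32)$ddGRounded   # 2.0 kcal/mol
#' @export
barrierReduction <- function(foldChange, temperature = 293.15, kT = NULL) {
  if (foldChange <= 0) stop("fold change must be positive")
  if (is.null(kT)) kT <- R_KCAL * temperature
  ddG <- kT * log(foldChange)
  list(foldChange = foldChange, temperature = temperature, ddG = ddG,
       ddGRounded = round(ddG, 1))
}

#' Mean first passage time from a rate estimate
#'
#' `MFPT = 1/k`, in the reciprocal of the rate's time unit, with the s.e.m.
#' propagated as `sem_k / k^2`.
#'
#' @param rate a [RateEstimate-class] (or a bare positive rate).
#' @return list with `mfpt` and `sem`.
#' @export
mfptFromRate <- function(rate) {
  k <- if (is(rate, "RateEstimate")) rate@k else rate
  if (k <= 0) stop("zero rate: MFPT undefined")
  sem <- if (is(rate, "RateEstimate") && !is.na(rate@sem))
    rate@sem / k^2 else NA_real_
  list(mfpt = 1 / k, sem = sem)
}

#' WE-versus-brute-force efficiency report
#'
#' `S = (MFPT x number of independent switching events) / (aggregate WE
#' simulated time)`: the expected brute-force cost of harvesting the same
#' number of independent events divided by what the WE run actually spent.
#'
#' @param rate a [RateEstimate-class] carrying the event count and aggregate
#'   simulated time of its archives.
#' @return list with `S`, `bruteForceCost`, `weCost`, `nEvents`, `mfpt`.
#' @export
weEfficiency <- function(rate) {
  stopifnot(is(rate, "RateEstimate"))
  if (rate@nEvents == 0) stop("zero switching events: efficiency undefined")
  mfpt <- 1 / rate@k
  brute <- mfpt * rate@nEvents
  list(S = brute / rate@totalTime, bruteForceCost = brute,
       weCost = rate@totalTime, nEvents = rate@nEvents, mfpt = mfpt)
}
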