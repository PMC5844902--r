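#' @include kinetics.R
NULL

#' Calibrate the uniform contact strength against a target stability
#'
#' Finds the single well-depth scalar `eps` at which a two-state component's
#' folding free energy matches `targetDG`, by monotone bracketing over
#' `eps` (stability decreases monotonically as contacts deepen): the next
#' trial point interpolates the bracketing pair (false position), falling
#' back to the bracket midpoint when interpolation stalls, which converges
#' in a handful of evaluations on the smooth, steep dG(eps) response of
#' cooperative folders.  The stability at each trial `eps` is supplied by
#' `stabilityFun` — typically an equilibrium-WE estimate on the component
#' (see [makeToyHairpin()] for a wired-up example), but any estimator
#' satisfying the stability contract works.
#'
#' @param stabilityFun function(eps) returning the estimated folding free
#'   energy (same energy unit as `targetDG`; negative = folded favoured).
#' @param targetDG target folding free energy (< 0 for a stable folder, 0
#'   for the folding midpoint).
#' @param tolerance convergence tolerance on `|dG - targetDG|`.
#' @param epsBounds search bracket for `eps`.
#' @param maxEvals evaluation budget before giving up.
#' @return list with `eps`, `dG`, and the search `trace` (data.frame of
#'   eps/dG pairs).
#' @export
calibrateContactStrength <- function(stabilityFun, targetDG,
                                     tolerance = 0.3,
                                     epsBounds = c(0.2, 5),
                                     maxEvals = 24L) {
  lo <- epsBounds[1L]; hi <- epsBounds[2L]
  trace <- data.frame(eps = numeric(0), dG = numeric(0))
  evalAt <- function(eps) {
    dG <- stabilityFun(eps)
    trace[nrow(trace) + 1L, ] <<- c(eps, dG)
    dG
  }
  dLo <- evalAt(lo)   # weak contacts: least stable (largest dG)
  dHi <- evalAt(hi)   # strong contacts: most stable (smallest dG)
  if (abs(dLo - targetDG) <= tolerance)
    return(list(eps = lo, dG = dLo, trace = trace))
  if (abs(dHi - targetDG) <= tolerance)
    return(list(eps = hi, dG = dHi, trace = trace))
  if (!(dLo > targetDG && dHi < targetDG)) {
    err <- structure(class = c("calibrationFailure", "error", "condition"),
                     list(message = sprintf(
                       paste0("calibration failure: target dG %.3g not ",
                              "bracketed by eps in [%g, %g] ",
                              "(dG range [%.3g, %.3g])"),
                       targetDG, lo, hi, dHi, dLo),
                       call = sys.call(-1), trace = trace))
    stop(err)
  }
  for (it in seq_len(maxEvals - 2L)) {
    # false position on the bracketing pair, clipped away from the ends;
    # bisection fallback every third step guards against one-sided stalls
    mid <- lo + (targetDG - dLo) * (hi - lo) / (dHi - dLo)
    if (it %% 3L == 0L || !is.finite(mid))
      mid <- (lo + hi) / 2
    mid <- min(max(mid, lo + 0.02 * (hi - lo)), hi - 0.02 * (hi - lo))
    dMid <- evalAt(mid)
    if (abs(dMid - targetDG) <= tolerance)
      return(list(eps = mid, dG = dMid, trace = trace, converged = TRUE))
    if (dMid > targetDG) { lo <- mid; dLo <- dMid }
    else { hi <- mid; dHi <- dMid }
  }
  mid <- (lo + hi) / 2
  dMid <- evalAt(mid)
  list(eps = mid, dG = dMid, trace = trace,
       converged = abs(dMid - targetDG) <= tolerance)
}

#' Rescale every contact well depth of a model
#'
#' Multiplies all native-contact well depths by `eps / <current uniform
#' depth>`; used to apply a calibrated uniform strength.
#'
#' @param model an [AFFModel-class].
#' @param eps new uniform well depth.
#' @return the rescaled model.
#' @export
setContactStrength <- function(model, eps) {
  stopifnot(is(model, "AFFModel"), eps >= 0)
  pos <- model@contactMap@eps > 0
  model@contactMap@eps[pos] <- eps
  validObject(model)
  model
}
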