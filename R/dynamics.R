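#' @include aff.R
NULL

#' Gas constant in kcal mol-1 K-1
#' @export
R_KCAL <- 1.987e-3

#' Integrator configuration for overdamped Brownian dynamics
#'
#' In real units energies are kcal/mol, lengths Angstrom, times ps and
#' `kT = R * temperature`; in reduced units `kT = 1` and the time unit is
#' arbitrary.  The segment length `tau` and `sampleInterval` must be integer
#' multiples of the timestep.
#'
#' @param temperature kelvin (default 293.15, i.e. 20 C); used in real units.
#' @param timestep integration step (ps, or reduced time).
#' @param D per-bead diffusion coefficient (A^2 / time unit; default 0.02
#'   A^2/ps in real units, 1 in reduced units).
#' @param tau segment length (default 100 ps real, 0.5 reduced).
#' @param sampleInterval sampling interval within a segment (default 50 ps
#'   real; `tau` reduced, i.e. end frames only).
#' @param maxDisp per-coordinate displacement sanity bound per step (A);
#'   exceeding it raises a timestep-too-large error.
#' @param units `"real"` or `"reduced"`.
#' @param kT explicit thermal energy override (reduced units default 1).
#' @param storeInitial store the segment's initial frame as the first sample.
#' @return a classed list of integrator settings with derived `kT` and step
#'   counts.
#' @export
integratorConfig <- function(temperature = 293.15,
                             timestep = if (units == "real") 0.1 else 0.005,
                             D = if (units == "real") 0.02 else 1,
                             tau = if (units == "real") 100 else 0.5,
                             sampleInterval = if (units == "real") 50 else tau,
                             maxDisp = 2.0, units = c("real", "reduced"),
                             kT = NULL, storeInitial = FALSE) {
  units <- match.arg(units)
  stopifnot(timestep > 0, tau > 0, sampleInterval > 0)
  nsteps <- tau / timestep
  nsamp <- sampleInterval / timestep
  if (abs(nsteps - round(nsteps)) > 1e-8)
    stop("tau must be an integer multiple of timestep")
  if (abs(nsamp - round(nsamp)) > 1e-8)
    stop("sampleInterval must be an integer multiple of timestep")
  if (is.null(kT)) kT <- if (units == "real") R_KCAL * temperature else 1
  structure(list(temperature = temperature, timestep = timestep, D = D,
                 tau = tau, sampleInterval = sampleInterval,
                 maxDisp = maxDisp, units = units, kT = kT,
                 nsteps = as.integer(round(nsteps)),
                 sampleEvery = as.integer(round(nsamp)),
                 storeInitial = storeInitial),
            class = "IntegratorConfig")
}

#' @rdname potentialEnergy
#' @export
setMethod("potentialEnergy", "AFFModel", function(model, coords) {
  stopifnot(all(is.finite(coords)), nrow(coords) == nBeads(model))
  e <- cpp_energy(.goModelList(model), coords)
  if (!is.finite(e))
    stop("non-finite energy: beads overlap below the hard floor")
  e
})

#' @rdname modelForces
#' @export
setMethod("modelForces", "AFFModel", function(model, coords) {
  stopifnot(all(is.finite(coords)), nrow(coords) == nBeads(model))
  r <- cpp_energy_forces(.goModelList(model), coords)
  if (!is.finite(r$energy))
    stop("non-finite energy: beads overlap below the hard floor")
  r$forces
})

#' One overdamped Brownian step
#'
#' `x <- x + (D dt / kT) F + xi` with `xi ~ N(0, 2 D dt)` independently per
#' coordinate.  Draws from R's RNG, so a fixed seed gives bitwise
#' reproducible trajectories.
#'
#' @param coords coordinate matrix (or vector).
#' @param forces matching force matrix (or vector).
#' @param config an [integratorConfig()].
#' @return updated coordinates.
#' @export
brownianStep <- function(coords, forces, config) {
  dt <- config$timestep
  disp <- (config$D * dt / config$kT) * forces +
    stats::rnorm(length(coords), sd = sqrt(2 * config$D * dt))
  if (any(abs(disp) > config$maxDisp))
    stop("timestep too large: per-step displacement exceeds the sanity bound")
  coords + disp
}

#' Propagator for a dual-frame AFF model
#'
#' Bundles an [AFFModel-class] with an [integratorConfig()] into an object
#' satisfying the segment-propagation contract used by the WE engine:
#' [runSegment()] advances exactly `tau` of Brownian dynamics and
#' [computeProgress()] returns the `(rmsd_N, rmsd_Nprime)` progress
#' coordinate.
#'
#' @slot model the [AFFModel-class].
#' @slot config the integrator configuration list.
#' @export
setClass("GoPropagator",
         representation(model = "AFFModel", config = "list"))

#' Create an AFF-model propagator
#'
#' @param model an [AFFModel-class].
#' @param config an [integratorConfig()].
#' @return a [GoPropagator-class].
#' @export
goPropagator <- function(model, config) {
  cf <- unclass(config)
  cf$mlist <- .goModelList(model)   # parameter tables cached once
  new("GoPropagator", model = model, config = cf)
}

#' @rdname runSegment
#' @export
setMethod("runSegment", "GoPropagator", function(propagator, coords) {
  cf <- propagator@config
  ml <- if (is.null(cf$mlist)) .goModelList(propagator@model) else cf$mlist
  out <- cpp_propagate(ml, coords, cf$nsteps,
                       cf$timestep, cf$D, cf$kT, cf$sampleEvery, cf$maxDisp)
  samples <- out$samples
  times <- seq_along(samples) * cf$sampleEvery * cf$timestep
  if (isTRUE(cf$storeInitial)) {
    samples <- c(list(coords), samples)
    times <- c(0, times)
  }
  list(end = out$end, samples = samples, times = times)
})

#' @rdname computeProgress
#' @export
setMethod("computeProgress", "GoPropagator", function(propagator, coords) {
  m <- propagator@model
  frameRMSD <- function(idx, ref) {
    if (length(idx) < 3L)
      stop("undefined superposition: frame has fewer than 3 residues")
    cpp_rmsd(coords[idx, , drop = FALSE], ref[idx, , drop = FALSE])
  }
  if (length(m@topology@frameNprime) == 0L)   # plain single-frame folder
    return(c(rmsd_N = frameRMSD(m@topology@frameN, m@refN)))
  c(rmsd_N = frameRMSD(m@topology@frameN, m@refN),
    rmsd_Nprime = frameRMSD(m@topology@frameNprime, m@refNprime))
})

#' @rdname progressDim
#' @export
setMethod("progressDim", "GoPropagator", function(propagator)
  if (length(propagator@model@topology@frameNprime) == 0L) 1L else 2L)

#' @rdname initialConfigurations
#' @export
setMethod("initialConfigurations", "GoPropagator", function(propagator, n) {
  pool <- propagator@config$initialPool
  if (!is.null(pool)) {   # pre-equilibrated state ensemble: weighted draws
    idx <- sample.int(length(pool$frames), n, replace = TRUE,
                      prob = pool$weights)
    return(pool$frames[idx])
  }
  x0 <- propagator@config$initialCoords
  if (is.null(x0)) x0 <- propagator@model@refN
  replicate(n, x0, simplify = FALSE)
})

#' Minimized C-alpha RMSD after optimal superposition
#'
#' Kabsch superposition (proper rotations only) of `x` onto `ref`.
#'
#' @param x,ref n x 3 coordinate matrices over the same beads.
#' @return RMSD in Angstrom.
#' @export
rmsdKabsch <- function(x, ref) cpp_rmsd(as.matrix(x), as.matrix(ref))
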