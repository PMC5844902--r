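#' @include AllClasses.R
NULL

#' Number of beads (residues) in an object
#'
#' @param x a [BeadStructure-class], [AFFModel-class] or other object with a
#'   bead dimension.
#' @return integer scalar.
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))

#' Bead coordinates
#'
#' @param x an object carrying C-alpha bead coordinates.
#' @return numeric matrix with one row per bead and columns x, y, z (Angstrom).
#' @export
setGeneric("beadCoords", function(x) standardGeneric("beadCoords"))

#' Contact map of a model
#'
#' @param x an [AFFModel-class] or other object holding native contacts.
#' @return a [ContactMap-class].
#' @export
setGeneric("contacts", function(x) standardGeneric("contacts"))

#' AFF topology of a model
#'
#' @param x an [AFFModel-class].
#' @return an [AFFTopology-class].
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' Total potential energy of a configuration
#'
#' Sum of bonded (bond/angle/dihedral), native-contact and excluded-volume
#' terms of the implemented energy function.
#'
#' @param model an [AFFModel-class].
#' @param coords numeric n x 3 coordinate matrix (Angstrom).
#' @return energy, in the model's energy unit (kcal/mol in real units,
#'   kT in reduced units).
#' @export
setGeneric("potentialEnergy",
           function(model, coords) standardGeneric("potentialEnergy"))

#' Forces (negative energy gradient) on every bead
#'
#' @inheritParams potentialEnergy
#' @return numeric n x 3 matrix of force components (energy unit / Angstrom).
#' @export
setGeneric("modelForces",
           function(model, coords) standardGeneric("modelForces"))

#' Propagate one fixed-duration dynamics segment
#'
#' Runs exactly `tau` of overdamped Brownian dynamics from `coords` under the
#' propagator's integrator configuration, storing samples every
#' `sampleInterval`.
#'
#' @param propagator a propagator object (see [goPropagator()],
#'   [makeDoubleWell()]).
#' @param coords starting configuration (n x 3 matrix, or numeric scalar for
#'   1-D propagators).
#' @return a list with elements `end` (final configuration), `samples`
#'   (list of stored configurations), `times` (sample time offsets, in the
#'   propagator's time unit).
#' @export
setGeneric("runSegment",
           function(propagator, coords) standardGeneric("runSegment"))

#' Progress coordinate of a configuration
#'
#' For dual-frame AFF propagators this is the pair of minimized C-alpha RMSDs
#' `(rmsd_N, rmsd_Nprime)` of the two frames from their folded reference
#' conformations; for 1-D fixtures it is the position itself.
#'
#' @inheritParams runSegment
#' @return numeric vector (length = progress dimension).
#' @export
setGeneric("computeProgress",
           function(propagator, coords) standardGeneric("computeProgress"))

#' Dimension of the progress coordinate
#' @inheritParams runSegment
#' @return integer scalar.
#' @export
setGeneric("progressDim",
           function(propagator) standardGeneric("progressDim"))

#' Draw initial-state configurations
#'
#' @inheritParams runSegment
#' @param n number of configurations to draw.
#' @return list of `n` configurations.
#' @export
setGeneric("initialConfigurations",
           function(propagator, n) standardGeneric("initialConfigurations"))

#' Number of WE iterations stored in an archive
#' @param x a [WEArchive-class].
#' @return integer scalar.
#' @export
setGeneric("nIterations", function(x) standardGeneric("nIterations"))

#' Recycled probability flux per iteration
#'
#' Weight recycled into the initial state at each WE iteration (zero in
#' equilibrium mode).
#'
#' @param x a [WEArchive-class].
#' @return numeric vector, one entry per iteration.
#' @export
setGeneric("recycledFlux", function(x) standardGeneric("recycledFlux"))

#' Total walker weight after every iteration
#'
#' Resampling and recycling move weight but never create or destroy it, so
#' this should remain 1 to within floating-point accumulation error.
#'
#' @param x a [WEArchive-class].
#' @return numeric vector, one entry per iteration.
#' @export
setGeneric("weightTotals", function(x) standardGeneric("weightTotals"))
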