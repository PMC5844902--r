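#' @include contacts.R
NULL

# Map a parent-chain residue index into the construct for the N' (CP) frame:
# duplicated residues use the N-terminal copy, the rest keep their original
# (offset) position.
.mapNprime <- function(w, dup, offset) {
  ifelse(w >= dup[1L] & w <= dup[2L], w - dup[1L] + 1L, w + offset)
}

#' Assemble a dual-frame AFF model from a parent structure
#'
#' Builds the construct `duplicated segment + linker + full parent chain`,
#' maps the parent's native contacts onto both frames (the N frame uses the
#' original copy of the duplicated segment; the N' frame uses the N-terminal
#' copy), tags contacts lying entirely in the shared segment once, derives
#' bonded reference values (bond lengths, angles, dihedrals) from the parent
#' geometry per segment, and places excluded volume between all non-native,
#' non-local pairs so that the two frames cannot fold simultaneously.
#'
#' Linker residues receive bonded terms only (bonds of length
#' `linkerBond`; no angle/dihedral terms involving a linker bead and no
#' native contacts), keeping the linker flexible.
#'
#' @param wt parent-chain [BeadStructure-class].
#' @param wtContacts parent-chain [ContactMap-class] from
#'   [computeNativeContacts()].
#' @param dupRange inclusive 1-based interval of duplicated parent residues
#'   (length-2 integer vector), or `NULL` for a degenerate (no-duplication)
#'   construct.
#' @param linkerLength number of linker residues (>= 0).
#' @param kb,ka,kd1,kd3 bonded force constants (defaults 20 energy/A^2,
#'   10 energy/rad^2, 0.5, 0.25 energy).
#' @param evSigma,evEps excluded-volume diameter (A) and prefactor.
#' @param linkerBond linker bond length (A).
#' @param units `"real"` or `"reduced"`.
#' @return an [AFFModel-class].
#' @examples
#' toy <- makeToyHairpin(nBeads = 20, calibrate = FALSE)
#' m <- buildAFFModel(toy$structure, toy$contacts,
#'                    dupRange = c(11L, 20L), linkerLength = 2L)
#' topology(m)
#' @export
buildAFFModel <- function(wt, wtContacts, dupRange, linkerLength,
                          kb = 20, ka = 10, kd1 = 0.5, kd3 = 0.25,
                          evSigma = 4.0, evEps = 1.0, linkerBond = 3.8,
                          units = "reduced") {
  stopifnot(is(wt, "BeadStructure"), is(wtContacts, "ContactMap"),
            linkerLength >= 0)
  wtn <- nBeads(wt)
  if (is.null(dupRange) || length(dupRange) == 0L) dupRange <- c(0L, -1L)
  dupRange <- as.integer(dupRange)
  ndup <- max(0L, dupRange[2L] - dupRange[1L] + 1L)
  if (ndup > 0L && (dupRange[1L] < 1L || dupRange[2L] > wtn))
    stop("duplicated_range must lie within the parent chain")
  linkerLength <- as.integer(linkerLength)
  offset <- ndup + linkerLength
  total <- wtn + offset

  frameN <- offset + seq_len(wtn)
  shared <- offset + setdiff(seq_len(wtn), seq(dupRange[1L], length.out = ndup))
  frameNp <- if (ndup > 0L) sort(.mapNprime(seq_len(wtn), dupRange, offset))
             else integer(0)
  topo <- new("AFFTopology", wtLength = wtn, dupRange = dupRange,
              linkerLength = linkerLength, totalLength = total,
              frameN = frameN, frameNprime = frameNp,
              shared = if (ndup > 0L) shared else integer(0))

  X <- wt@coords
  centroid <- colMeans(X)

  # straight-ish dangling tail with a small zig-zag (avoids exactly
  # collinear angle references), spacing `linkerBond`, pointing away from
  # the parent centroid from the attachment bead
  tailCoords <- function(anchor, n) {
    d <- anchor - centroid
    nd <- sqrt(sum(d^2))
    d <- if (nd < 1e-8) c(1, 0, 0) else d / nd
    perp <- if (abs(d[3]) < 0.9) c(-d[2], d[1], 0) else c(0, -d[3], d[2])
    perp <- perp / sqrt(sum(perp^2))
    t(vapply(seq_len(n), function(k)
      anchor + k * linkerBond * d + 0.6 * (k %% 2) * perp, numeric(3)))
  }

  # reference conformation with frame N folded: parent geometry at its
  # offset position, copy + linker dangling off the parent N-terminus
  refN <- matrix(NA_real_, total, 3)
  refN[frameN, ] <- X
  if (offset > 0L)
    refN[offset:1L, ] <- tailCoords(X[1L, ], offset)

  # reference with frame N' folded: copy adopts the duplicated segment's
  # parent geometry, shared part unchanged, displaced original copy dangles
  # off the end of the shared segment; linker bridges copy -> shared start
  refNp <- refN
  if (ndup > 0L) {
    dupIdx <- seq(dupRange[1L], dupRange[2L])
    refNp[seq_len(ndup), ] <- X[dupIdx, ]
    orphan <- offset + dupIdx
    anchorIdx <- if (dupRange[1L] > 1L) dupRange[1L] - 1L else dupRange[2L] + 1L
    if (anchorIdx >= 1L && anchorIdx <= wtn) {
      tail <- tailCoords(X[anchorIdx, ], ndup)
      refNp[orphan, ] <- tail
    }
    if (linkerLength > 0L) {
      from <- refNp[ndup, ]
      toIdx <- offset + setdiff(seq_len(wtn), dupIdx)[1L]
      to <- refNp[toIdx, ]
      for (k in seq_len(linkerLength))
        refNp[ndup + k, ] <- from + (to - from) * k / (linkerLength + 1) +
          c(0, 0, 1.5)
    }
  }

  isLinker <- function(idx) idx > ndup & idx <= offset
  # bonds between consecutive construct beads; r0 from the parent geometry
  # for intra-segment bonds, linkerBond when a linker bead is involved
  bi <- seq_len(total - 1L)
  bondR0 <- vapply(bi, function(i) {
    j <- i + 1L
    if (isLinker(i) || isLinker(j) ||
        (i == ndup && ndup > 0L) || (i == offset && offset > 0L && ndup == 0L))
      return(linkerBond)
    if (j <= ndup) {                       # within the copy
      w <- seq(dupRange[1L], dupRange[2L])
      return(sqrt(sum((X[w[i], ] - X[w[j], ])^2)))
    }
    if (i == offset) return(linkerBond)    # junction linker -> parent
    sqrt(sum((X[i - offset, ] - X[j - offset, ])^2))
  }, numeric(1))
  bonds <- cbind(bi, bi + 1L, bondR0)

  wtAngle <- function(w1, w2, w3) {
    a <- X[w1, ] - X[w2, ]; b <- X[w3, ] - X[w2, ]
    acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
  }
  wtDihedral <- function(w1, w2, w3, w4) {
    b1 <- X[w2, ] - X[w1, ]; b2 <- X[w3, ] - X[w2, ]; b3 <- X[w4, ] - X[w3, ]
    cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])
    m <- cr(b1, b2); nn <- cr(b2, b3)
    atan2(sum(cr(m, nn) * b2) / sqrt(sum(b2^2)), sum(m * nn))
  }
  segIdx <- function(cidx) {
    # parent index of a construct bead, NA for linker
    if (cidx <= ndup) return(dupRange[1L] + cidx - 1L)
    if (cidx <= offset) return(NA_integer_)
    cidx - offset
  }
  angles <- NULL
  for (i in seq_len(max(0L, total - 2L))) {
    w <- vapply(i:(i + 2L), segIdx, integer(1))
    if (anyNA(w)) next
    inCopy <- all(i:(i + 2L) <= ndup)
    inWT <- all(i:(i + 2L) > offset)
    if (!inCopy && !inWT) next
    angles <- rbind(angles, c(i, i + 1L, i + 2L, wtAngle(w[1], w[2], w[3])))
  }
  dihedrals <- NULL
  for (i in seq_len(max(0L, total - 3L))) {
    w <- vapply(i:(i + 3L), segIdx, integer(1))
    if (anyNA(w)) next
    inCopy <- all(i:(i + 3L) <= ndup)
    inWT <- all(i:(i + 3L) > offset)
    if (!inCopy && !inWT) next
    dihedrals <- rbind(dihedrals,
                       c(i, i + 1L, i + 2L, i + 3L,
                         wtDihedral(w[1], w[2], w[3], w[4])))
  }
  if (is.null(angles)) angles <- matrix(numeric(0), 0, 4)
  if (is.null(dihedrals)) dihedrals <- matrix(numeric(0), 0, 5)

  # contacts: N frame (original copy), N' frame (remapped), shared once
  wi <- wtContacts@i; wj <- wtContacts@j
  inDup <- function(w) ndup > 0L & w >= dupRange[1L] & w <= dupRange[2L]
  ci <- cj <- integer(0); cr0 <- ce <- numeric(0); ctag <- character(0)
  for (t in seq_along(wi)) {
    bothShared <- ndup > 0L && !inDup(wi[t]) && !inDup(wj[t])
    # N-frame placement (original copy)
    ci <- c(ci, wi[t] + offset); cj <- c(cj, wj[t] + offset)
    cr0 <- c(cr0, wtContacts@r0[t]); ce <- c(ce, wtContacts@eps[t])
    ctag <- c(ctag, if (bothShared) "shared" else "N")
    if (!bothShared && ndup > 0L) {
      a <- .mapNprime(wi[t], dupRange, offset)
      b <- .mapNprime(wj[t], dupRange, offset)
      ci <- c(ci, min(a, b)); cj <- c(cj, max(a, b))
      cr0 <- c(cr0, wtContacts@r0[t]); ce <- c(ce, wtContacts@eps[t])
      ctag <- c(ctag, "Nprime")
    }
  }
  if (anyDuplicated(paste(ci, cj)))
    stop("construction error: remapped contact indices overlap")
  minSep <- if (length(ci)) min(cj - ci) else wtContacts@minSeparation
  cm <- new("ContactMap", i = as.integer(ci), j = as.integer(cj),
            r0 = cr0, eps = ce, frameTag = ctag,
            cutoff = wtContacts@cutoff,
            minSeparation = min(wtContacts@minSeparation,
                                as.integer(minSep)))

  beads <- new("BeadStructure", coords = refN,
               residueIndex = seq_len(total),
               residueName = rep("GLY", total))
  new("AFFModel", topology = topo, beads = beads, contactMap = cm,
      bonds = unname(bonds), angles = unname(angles),
      dihedrals = unname(dihedrals),
      kb = kb, ka = ka, kd1 = kd1, kd3 = kd3,
      evSigma = evSigma, evEps = evEps,
      refN = refN, refNprime = refNp,
      mutEps = numeric(length(cm@i)),
      mutations = character(0), ligandBias = list(), units = units)
}

#' @describeIn buildAFFModel topology accessor.
#' @param x an `AFFModel`.
#' @export
setMethod("topology", "AFFModel", function(x) x@topology)

#' @describeIn buildAFFModel contact-map accessor.
#' @export
setMethod("contacts", "AFFModel", function(x) x@contactMap)

#' @describeIn buildAFFModel number of construct beads.
#' @export
setMethod("nBeads", "AFFModel", function(x) x@topology@totalLength)

#' @describeIn buildAFFModel reference (frame-N folded) coordinates.
#' @export
setMethod("beadCoords", "AFFModel", function(x) x@beads@coords)

setMethod("show", "AFFModel", function(object) {
  topo <- object@topology
  cat(sprintf(
    "AFFModel: %d beads (parent %d + duplicated %d + linker %d), %s units\n",
    topo@totalLength, topo@wtLength,
    max(0L, topo@dupRange[2L] - topo@dupRange[1L] + 1L),
    topo@linkerLength, object@units))
  tags <- table(object@contactMap@frameTag)
  cat("  contacts:", paste(names(tags), tags, sep = "=", collapse = ", "),
      "\n")
  if (length(object@mutations))
    cat("  mutations:", paste(object@mutations, collapse = ", "), "\n")
  if (length(object@ligandBias))
    cat(sprintf("  ligand bias: frame %s, scale %.2f\n",
                object@ligandBias$frame, object@ligandBias$strengthScale))
})

setMethod("show", "AFFTopology", function(object) {
  cat(sprintf(
    "AFFTopology: parent %d, duplicated %d-%d, linker %d -> construct %d\n",
    object@wtLength, object@dupRange[1L], object@dupRange[2L],
    object@linkerLength, object@totalLength))
})

#' Specify an in-silico underpacking mutation
#'
#' Delete-attractive mode: all favourable native interactions of the parent
#' residue are removed (the idealized maximum-underpacking scenario);
#' excluded volume is retained.
#'
#' @param residueIndex construct residue index to mutate.
#' @param label mutation label (e.g. `"F66A"`).
#' @return a mutation specification list.
#' @export
mutationSpec <- function(residueIndex, label = paste0("X", residueIndex)) {
  list(residueIndex = as.integer(residueIndex), label = label,
       mode = "delete-attractive")
}

#' Apply a delete-attractive mutation to a model
#'
#' Sets the well depth of every native contact involving the residue to
#' zero; the pair retains the repulsive core of its well (excluded volume),
#' so the mutation removes attraction only and can never lower the energy
#' of any configuration.  Bonded terms are unchanged.  Returns a new model;
#' applying the same specification twice is idempotent.
#'
#' @param model an [AFFModel-class].
#' @param spec a [mutationSpec()].
#' @return the mutated [AFFModel-class].
#' @export
applyMutation <- function(model, spec) {
  stopifnot(is(model, "AFFModel"))
  r <- spec$residueIndex
  if (length(r) != 1L || r < 1L || r > nBeads(model))
    stop("unknown residue index: ", r)
  hit <- model@contactMap@i == r | model@contactMap@j == r
  live <- hit & model@contactMap@eps > 0
  model@mutEps[live] <- model@contactMap@eps[live]
  model@contactMap@eps[hit] <- 0
  if (!spec$label %in% model@mutations)
    model@mutations <- c(model@mutations, spec$label)
  validObject(model)
  model
}

#' Specify a ligand bias on one frame
#'
#' Minimal representation of preferential ligand stabilization of the
#' binding-competent frame: a uniform multiplicative scaling of the well
#' depths of that frame's contacts involving the binding-loop residues.
#'
#' @param frame `"N"` or `"Nprime"`.
#' @param strengthScale dimensionless multiplier >= 1; 1 reproduces the apo
#'   model exactly.
#' @param residues construct residue indices of the binding loop; affected
#'   pairs are the frame's contacts touching these residues (all of the
#'   frame's contacts when `NULL`).
#' @param pairs optional explicit two-column (i, j) matrix of affected pairs;
#'   every listed pair must carry the stated frame's tag.
#' @return a ligand-bias specification list.
#' @export
ligandBias <- function(frame = c("N", "Nprime"), strengthScale = 1,
                       residues = NULL, pairs = NULL) {
  frame <- match.arg(frame)
  stopifnot(strengthScale >= 1)
  list(frame = frame, strengthScale = strengthScale, residues = residues,
       pairs = pairs)
}

#' Apply a ligand bias to a model
#'
#' Multiplies the well depths of the affected pairs by the bias strength;
#' every other term is unchanged.  Affected pairs must carry the stated
#' frame's tag.
#'
#' @param model an [AFFModel-class].
#' @param bias a [ligandBias()].
#' @return the biased [AFFModel-class].
#' @export
applyLigandBias <- function(model, bias) {
  stopifnot(is(model, "AFFModel"))
  tag <- model@contactMap@frameTag
  inFrame <- tag == bias$frame
  if (!any(inFrame)) stop("the ", bias$frame, " frame has no contacts")
  hit <- inFrame
  if (!is.null(bias$pairs)) {
    want <- paste(pmin(bias$pairs[, 1L], bias$pairs[, 2L]),
                  pmax(bias$pairs[, 1L], bias$pairs[, 2L]))
    have <- paste(model@contactMap@i, model@contactMap@j)
    hit <- have %in% want
    if (any(hit & !inFrame) || !all(want %in% have[inFrame]))
      stop("ligand bias lists a pair outside the stated frame")
  } else if (!is.null(bias$residues)) {
    touch <- model@contactMap@i %in% bias$residues |
      model@contactMap@j %in% bias$residues
    hit <- inFrame & touch
    if (!any(hit)) stop("no contacts of frame ", bias$frame,
                        " involve the given binding-loop residues")
  }
  model@contactMap@eps[hit] <- model@contactMap@eps[hit] * bias$strengthScale
  model@ligandBias <- bias
  validObject(model)
  model
}

# Flat parameter list handed to the compiled energy/force kernels.
# Native pairs whose eps has been zeroed by mutation keep the repulsive
# core of their well (WCA split) and are excluded from the generic
# excluded-volume list.
.goModelList <- function(model) {
  n <- nBeads(model)
  cm <- model@contactMap
  active <- cm@eps > 0
  mut <- model@mutEps > 0
  key <- function(i, j) (i - 1) * n + j
  nativeKeys <- key(cm@i[active | mut], cm@j[active | mut])
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep <- idx[, 2L] - idx[, 1L]
  cand <- idx[sep >= 3L, , drop = FALSE]
  ev <- cand[!(key(cand[, 1L], cand[, 2L]) %in% nativeKeys), , drop = FALSE]
  list(n = n,
       bonds = model@bonds, kb = model@kb,
       angles = model@angles, ka = model@ka,
       dihedrals = model@dihedrals, kd1 = model@kd1, kd3 = model@kd3,
       contacts = cbind(cm@i[active], cm@j[active], cm@r0[active],
                        cm@eps[active]),
       evpairs = ev, evSigma = model@evSigma, evEps = model@evEps,
       wca = cbind(cm@i[mut], cm@j[mut], cm@r0[mut], model@mutEps[mut]))
}

#' Native-contact energy of a configuration
#'
#' Sum of the 12-10 contact wells only (no bonded or excluded-volume terms);
#' equals minus the summed well depths when every contact sits at its native
#' distance.
#'
#' @param model an [AFFModel-class].
#' @param coords n x 3 coordinate matrix.
#' @return energy in the model's unit.
#' @export
contactEnergy <- function(model, coords) {
  cm <- model@contactMap
  if (!length(cm@i)) return(0)
  d <- sqrt(rowSums((coords[cm@i, , drop = FALSE] -
                     coords[cm@j, , drop = FALSE])^2))
  s <- cm@r0 / d
  sum(cm@eps * (5 * s^12 - 6 * s^10))
}
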