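#' @include AllGenerics.R
NULL

#' Construct a BeadStructure from coordinates
#'
#' @param coords numeric n x 3 matrix of C-alpha positions (Angstrom).
#' @param residueName character vector of 3-letter codes (recycled).
#' @return a [BeadStructure-class].
#' @export
beadStructure <- function(coords, residueName = "GLY") {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  new("BeadStructure", coords = coords,
      residueIndex = seq_len(nrow(coords)),
      residueName = rep_len(residueName, nrow(coords)))
}

#' @describeIn beadStructure number of beads.
#' @param x a `BeadStructure`.
#' @export
setMethod("nBeads", "BeadStructure", function(x) nrow(x@coords))

#' @describeIn beadStructure bead coordinate matrix.
#' @export
setMethod("beadCoords", "BeadStructure", function(x) x@coords)

setMethod("show", "BeadStructure", function(object) {
  cat("BeadStructure:", nrow(object@coords), "C-alpha beads\n")
})

#' Load a C-alpha bead model from PDB text
#'
#' Extracts one bead per residue at the C-alpha position of the requested
#' chain.  Alternate locations are resolved deterministically (highest
#' occupancy first, then lexicographic altloc label); residues are renumbered
#' 1..n in chain order.  Residues of the chain that carry atoms but no
#' C-alpha raise a gap error naming them.
#'
#' @param pdb PDB-format text (a single string or character vector of lines)
#'   or the path to a PDB file.
#' @param chain chain identifier (default `"A"`).
#' @return a [BeadStructure-class].
#' @examples
#' toy <- makeToyHairpin(nBeads = 16)
#' s <- loadStructure(toy$pdbText)
#' nBeads(s)
#' @export
loadStructure <- function(pdb, chain = "A") {
  path <- pdb
  if (length(pdb) > 1L || grepl("\n", pdb) || !file.exists(pdb)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(if (length(pdb) > 1L) pdb else strsplit(pdb, "\n")[[1L]], path)
  }
  p <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- p$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  avail <- sort(unique(at$chain))
  if (!chain %in% avail)
    stop("chain '", chain, "' not found; available chains: ",
         paste(avail, collapse = ", "))
  at <- at[at$chain == chain, , drop = FALSE]
  # residue identity = (resno, insert) in file order
  rid <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  resOrder <- unique(rid)
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing <- setdiff(resOrder, paste(ca$resno,
                                     ifelse(is.na(ca$insert), "", ca$insert)))
  if (length(missing))
    stop("gap: residues without a C-alpha atom in chain ", chain, ": ",
         paste(trimws(missing), collapse = ", "))
  pick <- lapply(resOrder, function(r) {
    rows <- ca[paste(ca$resno, ifelse(is.na(ca$insert), "", ca$insert)) == r,
               , drop = FALSE]
    occ <- ifelse(is.na(rows$o), 1, rows$o)
    alt <- ifelse(is.na(rows$alt), "", rows$alt)
    rows[order(-occ, alt)[1L], , drop = FALSE]
  })
  pick <- do.call(rbind, pick)
  if (nrow(pick) < 4L)
    stop("chain ", chain, " has fewer than 4 residues with C-alpha atoms")
  new("BeadStructure",
      coords = unname(as.matrix(pick[, c("x", "y", "z")])),
      residueIndex = seq_len(nrow(pick)),
      residueName = as.character(pick$resid))
}

#' Write a BeadStructure as minimal PDB text
#'
#' @param structure a [BeadStructure-class].
#' @param chain chain identifier to write.
#' @return character vector of PDB lines (ATOM records + END).
#' @export
writeStructurePDB <- function(structure, chain = "A") {
  stopifnot(is(structure, "BeadStructure"))
  xyz <- structure@coords
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(xyz)), structure@residueName, chain,
    structure@residueIndex, xyz[, 1], xyz[, 2], xyz[, 3])
  c(lines, "END")
}
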