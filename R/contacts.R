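#' @include AllGenerics.R
NULL

#' Compute the native contact map of a bead structure
#'
#' A residue pair (i, j) is a native contact when its sequence separation
#' `j - i` is at least `minSeparation` and its C-alpha distance is at most
#' `cutoff`.  `r0` is set to the native pair distance; well depths are set to
#' a uniform `eps` (a single calibration scalar, see
#' [calibrateContactStrength()]).
#'
#' @param structure a [BeadStructure-class].
#' @param cutoff distance cutoff in Angstrom (default 8.0, the common
#'   residue-level convention).
#' @param minSeparation minimum `j - i` (default 3).
#' @param eps uniform well depth assigned to every pair (default 1).
#' @return a [ContactMap-class] with frame tag `"untagged"`.
#' @examples
#' sq <- beadStructure(cbind(c(0, 5, 5, 0), c(0, 0, 5, 5), 0))
#' contactPairs(computeNativeContacts(sq, cutoff = 8, minSeparation = 3))
#' @export
computeNativeContacts <- function(structure, cutoff = 8.0,
                                  minSeparation = 3L, eps = 1.0) {
  stopifnot(is(structure, "BeadStructure"), cutoff > 0)
  d <- as.matrix(stats::dist(structure@coords))
  n <- nrow(d)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  sep <- idx[, 2L] - idx[, 1L]
  keep <- sep >= minSeparation & d[idx] <= cutoff
  idx <- idx[keep, , drop = FALSE]
  new("ContactMap",
      i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]),
      r0 = d[idx], eps = rep(eps, nrow(idx)),
      frameTag = rep("untagged", nrow(idx)),
      cutoff = cutoff, minSeparation = as.integer(minSeparation))
}

#' Contact map as a data frame
#'
#' @param map a [ContactMap-class].
#' @return data.frame with columns `i`, `j`, `r0`, `eps`, `frame_tag`.
#' @export
contactPairs <- function(map) {
  stopifnot(is(map, "ContactMap"))
  data.frame(i = map@i, j = map@j, r0 = map@r0, eps = map@eps,
             frame_tag = map@frameTag)
}

#' Export a contact map as TSV
#'
#' @param map a [ContactMap-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeContactMap <- function(map, file) {
  utils::write.table(contactPairs(map), file = file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", length(object@i), "native contacts",
      sprintf("(cutoff %.1f A, min separation %d)\n",
              object@cutoff, object@minSeparation))
  if (length(object@i))
    print(table(frame = object@frameTag))
})

nContacts <- function(map) length(map@i)
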