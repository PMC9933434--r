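# Canonical atom-order registry.  The Coulomb matrix is not permutation
# invariant, so the atom order for a given pigment type is fixed once and all
# inputs are reordered by atom name before descriptor construction.

.pigmentRegistry <- new.env(parent = emptyenv())

#' Register the canonical atom order for a pigment type
#'
#' @param pigmentType string tag, e.g. "CLA".
#' @param atomNames character vector giving the canonical atom-name order.
#' @param overwrite logical; re-registering with a different order requires
#'   \code{overwrite = TRUE}.
#' @return Invisibly, the registered atom-name vector.
#' @export
registerPigmentType <- function(pigmentType, atomNames, overwrite = FALSE) {
  existing <- .pigmentRegistry[[pigmentType]]
  if (!is.null(existing) && !identical(existing, atomNames) && !overwrite) {
    stop("pigment type '", pigmentType,
         "' already registered with a different atom order; ",
         "use overwrite = TRUE to replace it")
  }
  assign(pigmentType, as.character(atomNames), envir = .pigmentRegistry)
  invisible(atomNames)
}

#' Canonical atom order of a registered pigment type
#'
#' @param pigmentType string tag.
#' @return Character vector of atom names, or NULL when unregistered.
#' @export
canonicalAtomOrder <- function(pigmentType) {
  .pigmentRegistry[[pigmentType]]
}

#' Reorder a geometry's atoms into the canonical order of its pigment type
#'
#' A no-op for unregistered types (their first-seen order is taken as
#' canonical and registered).
#'
#' @param geom a [ChromophoreGeometry-class].
#' @return A ChromophoreGeometry in canonical atom order.
#' @export
canonicalizeGeometry <- function(geom) {
  canon <- canonicalAtomOrder(pigmentType(geom))
  if (is.null(canon)) {
    registerPigmentType(pigmentType(geom), atomNames(geom))
    return(geom)
  }
  if (identical(atomNames(geom), canon)) return(geom)
  idx <- match(canon, atomNames(geom))
  if (anyNA(idx) || length(canon) != nAtoms(geom)) {
    stop("atom names of geometry do not match the canonical order for ",
         "pigment type '", pigmentType(geom), "'")
  }
  ChromophoreGeometry(atomNames(geom)[idx], geom@elements[idx],
                      coordinates(geom)[idx, , drop = FALSE],
                      pigmentType(geom))
}
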