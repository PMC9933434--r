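# Descriptors: Coulomb matrix over heavy atoms for the pigment's internal
# geometry, and the MM electrostatic potential on the QM atoms for the
# environment.

#' Hydrogen-free Coulomb-matrix descriptor
#'
#' Encodes the internal geometry of a chromophore as the flattened upper
#' triangle of the Coulomb matrix, entries Z_i Z_j / r_ij over heavy atoms
#' only, in canonical atom order.  The constant diagonal is dropped, as is
#' every pair involving hydrogen: hydrogens add permutationally ambiguous,
#' nearly redundant entries and invite overfitting.
#'
#' The descriptor depends only on interatomic distances, so it is invariant
#' under rigid rotation, translation and reflection of the geometry.
#'
#' @param geom a [ChromophoreGeometry-class]; reordered into the canonical
#'   atom order of its pigment type before encoding.
#' @return Numeric vector of length nHeavy*(nHeavy-1)/2 with attribute
#'   \code{nHeavy}.  Empty (length 0) when fewer than two heavy atoms.
#' @examples
#' g <- ChromophoreGeometry(c("C1", "C2"), c("C", "C"),
#'                          rbind(c(0, 0, 0), c(1, 0, 0)), "PAIR")
#' coulombMatrix(g)  # single entry 6*6/1 = 36
#' @export
coulombMatrix <- function(geom) {
  geom <- canonicalizeGeometry(geom)
  heavy <- geom@elements != "H"
  xyz <- coordinates(geom)[heavy, , drop = FALSE]
  z <- atomicNumber(geom@elements[heavy])
  nh <- sum(heavy)
  if (nh < 2) {
    out <- numeric(0)
    attr(out, "nHeavy") <- nh
    return(out)
  }
  d <- crossDist(xyz, xyz)
  if (min(d[upper.tri(d)]) < 0.5) {
    stop("geometry error: heavy-atom pair closer than 0.5 Angstrom")
  }
  zz <- tcrossprod(z)
  cm <- (zz / d)[upper.tri(d)]
  attr(cm, "nHeavy") <- nh
  cm
}

#' MM electrostatic potential on the QM atoms
#'
#' Computes phi_i = sum_m q_m / r_im (e/Angstrom) at every QM atom, hydrogens
#' included, over the MM atoms retained by a residue-based cutoff: a residue
#' is kept iff the minimum distance from any of its atoms to any QM atom is
#' <= \code{cutoffA}, and residues are kept or dropped whole.
#'
#' @param geom a [ChromophoreGeometry-class].
#' @param env an [EnvironmentModel-class].
#' @param cutoffA residue-inclusion cutoff in Angstrom (default 30).
#' @return Numeric vector of potentials, one per QM atom, in e/Angstrom
#'   (multiply by [KE_EV_ANGSTROM] to form energies in eV).  All zero for an
#'   empty environment.
#' @export
mmPotential <- function(geom, env, cutoffA = 30) {
  stopifnot(cutoffA > 0)
  geom <- canonicalizeGeometry(geom)
  n <- nAtoms(geom)
  if (nSites(env) == 0) return(numeric(n))
  d <- crossDist(coordinates(geom), env@positions)  # n x m
  if (min(d) < 0.1) {
    stop("singularity error: environment atom within 0.1 Angstrom of a QM atom")
  }
  minByAtom <- apply(d, 2, min)
  resMin <- tapply(minByAtom, env@residueIds, min)
  keepRes <- as.integer(names(resMin)[resMin <= cutoffA])
  keep <- env@residueIds %in% keepRes
  if (!any(keep)) return(numeric(n))
  as.numeric((1 / d[, keep, drop = FALSE]) %*% env@charges[keep])
}

#' Potential-potential similarity (interaction weight)
#'
#' Inner product of two potential descriptors; the magnitude of the QM-MM
#' interaction energy that weights the nonlinear term of the composite shift
#' kernel.
#'
#' @param phi,phi2 numeric potential descriptors of equal length (e/Angstrom).
#' @return Scalar inner product.
#' @export
interactionWeight <- function(phi, phi2) {
  if (length(phi) != length(phi2)) {
    stop("potential descriptors differ in length")
  }
  sum(phi * phi2)
}
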