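#' Coulomb constant in eV Angstrom per elementary charge squared
#'
#' Conversion factor applied at every energy-forming step: distances are kept
#' in Angstrom, charges in elementary-charge units, potentials in e/Angstrom,
#' and energies in eV.
#'
#' @format A length-one numeric, 14.3996454 eV A e^-2.
#' @export
KE_EV_ANGSTROM <- 14.3996454

# Pairwise Euclidean distances between the rows of two n x 3 matrices.
crossDist <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Element symbol -> atomic number for the elements that occur in practice.
.ELEMENT_Z <- c(
  H = 1L, He = 2L, Li = 3L, Be = 4L, B = 5L, C = 6L, N = 7L, O = 8L,
  F = 9L, Ne = 10L, Na = 11L, Mg = 12L, Al = 13L, Si = 14L, P = 15L,
  S = 16L, Cl = 17L, K = 19L, Ca = 20L, Fe = 26L, Zn = 30L, Br = 35L
)

atomicNumber <- function(element) {
  z <- .ELEMENT_Z[element]
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "))
  }
  unname(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
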