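#' @import methods
NULL

# ---------------------------------------------------------------------------
# ChromophoreGeometry
# ---------------------------------------------------------------------------

#' Chromophore geometry: the QM subsystem
#'
#' Labeled atoms with Cartesian coordinates in Angstrom.  Atom order for a
#' given pigment type is canonical and identical across all instances; see
#' [registerPigmentType()].
#'
#' @slot atomNames character, canonical per-type atom names.
#' @slot elements character, element symbols.
#' @slot coords numeric matrix (n x 3), Cartesian coordinates in Angstrom.
#' @slot pigmentType single string, categorical tag (e.g. "CLA", "CHB", "TOY").
#'
#' @exportClass ChromophoreGeometry
setClass("ChromophoreGeometry",
  representation(
    atomNames = "character",
    elements = "character",
    coords = "matrix",
    pigmentType = "character"
  )
)

setValidity("ChromophoreGeometry", function(object) {
  n <- length(object@atomNames)
  if (length(object@elements) != n) {
    return("atomNames and elements must have equal length")
  }
  if (!is.numeric(object@coords) || nrow(object@coords) != n ||
      ncol(object@coords) != 3) {
    return("coords must be a numeric n x 3 matrix congruent with atomNames")
  }
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@pigmentType) != 1) {
    return("pigmentType must be a single string")
  }
  if (n >= 2) {
    d <- crossDist(object@coords, object@coords)
    if (min(d[upper.tri(d)]) <= 0.5) {
      return("overlapping atoms: a pairwise distance is <= 0.5 Angstrom")
    }
  }
  TRUE
})

#' Construct a ChromophoreGeometry
#'
#' @param atomNames character vector of canonical atom names.
#' @param elements character vector of element symbols.
#' @param coords numeric n x 3 matrix, Angstrom.
#' @param pigmentType single string tag; one model is trained per type.
#' @return A [ChromophoreGeometry-class] object.
#' @examples
#' g <- ChromophoreGeometry(c("C1", "C2"), c("C", "C"),
#'                          rbind(c(0, 0, 0), c(1.4, 0, 0)), "TOY")
#' nAtoms(g)
#' @export
ChromophoreGeometry <- function(atomNames, elements, coords, pigmentType) {
  new("ChromophoreGeometry", atomNames = as.character(atomNames),
      elements = as.character(elements),
      coords = unname(as.matrix(coords)),
      pigmentType = as.character(pigmentType))
}

#' @describeIn ChromophoreGeometry-class number of atoms
#' @param x a ChromophoreGeometry
#' @export
nAtoms <- function(x) nrow(x@coords)

#' @describeIn ChromophoreGeometry-class coordinate matrix (n x 3, Angstrom)
#' @param object a ChromophoreGeometry
#' @export
coordinates <- function(object) object@coords

#' @describeIn ChromophoreGeometry-class atom name accessor
#' @export
atomNames <- function(object) object@atomNames

#' @describeIn ChromophoreGeometry-class pigment type tag accessor
#' @export
pigmentType <- function(object) object@pigmentType

setMethod("show", "ChromophoreGeometry", function(object) {
  cat("ChromophoreGeometry of type", object@pigmentType, "with",
      nAtoms(object), "atoms (",
      sum(object@elements != "H"), "heavy )\n")
})

# ---------------------------------------------------------------------------
# EnvironmentModel
# ---------------------------------------------------------------------------

#' Point-charge environment: the MM subsystem
#'
#' Point charges grouped into residues, with positions and optional isotropic
#' polarizabilities.
#'
#' @slot positions numeric matrix (m x 3), Angstrom.
#' @slot charges numeric, elementary-charge units.
#' @slot residueIds integer grouping key per atom.
#' @slot residueNames character per atom.
#' @slot polarizabilities numeric, Angstrom^3; length 0 when absent,
#'   otherwise one value (>= 0) per atom.
#'
#' @exportClass EnvironmentModel
setClass("EnvironmentModel",
  representation(
    positions = "matrix",
    charges = "numeric",
    residueIds = "integer",
    residueNames = "character",
    polarizabilities = "numeric"
  )
)

setValidity("EnvironmentModel", function(object) {
  m <- nrow(object@positions)
  if (ncol(object@positions) != 3 && m > 0) return("positions must be m x 3")
  if (length(object@charges) != m) return("charges length mismatch")
  if (length(object@residueIds) != m) return("residueIds length mismatch")
  if (length(object@residueNames) != m) return("residueNames length mismatch")
  if (!(length(object@polarizabilities) %in% c(0L, m))) {
    return("polarizabilities must be absent or one per atom")
  }
  if (length(object@polarizabilities) && any(object@polarizabilities < 0)) {
    return("polarizabilities must be >= 0")
  }
  if (m > 0 && !all(is.finite(object@positions))) {
    return("positions must be finite")
  }
  TRUE
})

#' Construct an EnvironmentModel
#'
#' @param positions numeric m x 3 matrix, Angstrom.
#' @param charges numeric, elementary charges.
#' @param residueIds integer residue grouping key per atom.
#' @param residueNames optional character per atom (default "RES").
#' @param polarizabilities optional numeric per atom, Angstrom^3.
#' @return An [EnvironmentModel-class] object.
#' @export
EnvironmentModel <- function(positions, charges, residueIds,
                             residueNames = NULL, polarizabilities = NULL) {
  positions <- unname(as.matrix(positions))
  if (length(positions) == 0) positions <- matrix(numeric(0), 0, 3)
  m <- nrow(positions)
  if (is.null(residueNames)) residueNames <- rep("RES", m)
  new("EnvironmentModel", positions = positions,
      charges = as.numeric(charges),
      residueIds = as.integer(residueIds),
      residueNames = as.character(residueNames),
      polarizabilities = as.numeric(polarizabilities %||% numeric(0)))
}

#' An empty environment (no charges)
#' @return An [EnvironmentModel-class] with zero atoms.
#' @export
emptyEnvironment <- function() {
  EnvironmentModel(matrix(numeric(0), 0, 3), numeric(0), integer(0))
}

#' @describeIn EnvironmentModel-class number of MM atoms
#' @param x an EnvironmentModel
#' @export
nSites <- function(x) nrow(x@positions)

#' @describeIn EnvironmentModel-class charge accessor (e)
#' @param object an EnvironmentModel
#' @export
charges <- function(object) object@charges

#' @describeIn EnvironmentModel-class residue id accessor
#' @export
residueIds <- function(object) object@residueIds

#' @describeIn EnvironmentModel-class polarizability accessor (A^3); numeric(0) when absent
#' @export
polarizabilities <- function(object) object@polarizabilities

#' @describeIn EnvironmentModel-class TRUE when per-atom polarizabilities are present
#' @export
isPolarizable <- function(object) length(object@polarizabilities) > 0

setMethod("show", "EnvironmentModel", function(object) {
  cat("EnvironmentModel:", nSites(object), "MM atoms in",
      length(unique(object@residueIds)), "residues;",
      if (isPolarizable(object)) "polarizable\n" else "fixed charges only\n")
})

#' Subset an environment by residue ids
#'
#' @param env an [EnvironmentModel-class].
#' @param ids integer residue ids to keep.
#' @return A new EnvironmentModel containing only atoms of those residues.
#' @export
subsetResidues <- function(env, ids) {
  keep <- env@residueIds %in% as.integer(ids)
  EnvironmentModel(env@positions[keep, , drop = FALSE], env@charges[keep],
                   env@residueIds[keep], env@residueNames[keep],
                   if (isPolarizable(env)) env@polarizabilities[keep])
}

#' Zero the charges of one residue, keeping its atoms
#'
#' Used by the residue-influence analysis: the residue's electrostatics is
#' turned off but the atom set (and hence any cutoff selection) is unchanged.
#'
#' @param env an [EnvironmentModel-class].
#' @param residueId integer id of the residue to silence.
#' @return A new EnvironmentModel with that residue's charges set to 0.
#' @export
zeroResidueCharges <- function(env, residueId) {
  if (!(as.integer(residueId) %in% env@residueIds)) {
    stop("unknown residue id: ", residueId)
  }
  q <- env@charges
  q[env@residueIds == as.integer(residueId)] <- 0
  EnvironmentModel(env@positions, q, env@residueIds, env@residueNames,
                   if (isPolarizable(env)) env@polarizabilities)
}

# ---------------------------------------------------------------------------
# KernelSpec / GPModel
# ---------------------------------------------------------------------------

#' Kernel specification for Gaussian-process models
#'
#' @slot kind one of "matern", "linear", "composite_shift".
#' @slot params named numeric: \code{sigma}, \code{l} for matern;
#'   \code{sigma1} for linear; \code{sigma1}, \code{sigma2}, \code{l} for
#'   composite_shift.  All must be > 0.  The Matern smoothness is a fixed
#'   constant of the build (nu = 5/2).
#' @exportClass KernelSpec
setClass("KernelSpec",
  representation(kind = "character", params = "numeric"))

setValidity("KernelSpec", function(object) {
  if (!object@kind %in% c("matern", "linear", "composite_shift")) {
    return("kind must be matern, linear or composite_shift")
  }
  need <- switch(object@kind,
    matern = c("sigma", "l"),
    linear = "sigma1",
    composite_shift = c("sigma1", "sigma2", "l"))
  if (!all(need %in% names(object@params))) {
    return(paste("missing hyperparameters:",
                 paste(setdiff(need, names(object@params)), collapse = ", ")))
  }
  if (any(object@params[need] <= 0)) {
    return("all amplitude/lengthscale hyperparameters must be > 0")
  }
  TRUE
})

#' Construct a KernelSpec
#'
#' @param kind "matern", "linear" or "composite_shift".
#' @param ... named hyperparameters (sigma, l, sigma1, sigma2 as applicable).
#' @return A [KernelSpec-class].
#' @examples
#' KernelSpec("matern", sigma = 0.05, l = 10)
#' @export
KernelSpec <- function(kind, ...) {
  new("KernelSpec", kind = kind, params = unlist(list(...)))
}

setMethod("show", "KernelSpec", function(object) {
  cat("KernelSpec<", object@kind, ">: ",
      paste(names(object@params), signif(object@params, 4),
            sep = "=", collapse = ", "), "\n", sep = "")
})

#' Trained Gaussian-process model state
#'
#' Holds everything needed to reproduce predictions: kernel spec, noise,
#' training descriptor bundles, expansion coefficients, prior mean, and the
#' Cholesky factor of the regularized Gram matrix (for posterior variances).
#'
#' @slot kernel a [KernelSpec-class].
#' @slot noise observation noise variance sigma^2 (>= 0), eV^2 for energy
#'   targets.
#' @slot trainX list of descriptor bundles (each a named list with elements
#'   \code{cm} and/or \code{pot}).
#' @slot alpha numeric expansion coefficients, one per training point.
#' @slot priorMean scalar prior mean (mean of targets, or 0).
#' @slot cholK upper-triangular Cholesky factor of K + (sigma^2 + jitter) I.
#' @slot metadata named list: pigmentType, target, schemaVersion, etc.
#' @exportClass GPModel
setClass("GPModel",
  representation(
    kernel = "KernelSpec",
    noise = "numeric",
    trainX = "list",
    alpha = "numeric",
    priorMean = "numeric",
    cholK = "matrix",
    metadata = "list"
  )
)

setValidity("GPModel", function(object) {
  n <- length(object@trainX)
  if (length(object@alpha) != n) {
    return("length(alpha) must equal the number of training inputs")
  }
  if (object@noise < 0) return("noise variance must be >= 0")
  if (length(object@priorMean) != 1) return("priorMean must be scalar")
  TRUE
})

#' @describeIn GPModel-class number of training points
#' @param object a GPModel
#' @export
nTraining <- function(object) length(object@trainX)

#' @describeIn GPModel-class kernel accessor
#' @export
kernelSpec <- function(object) object@kernel

setMethod("show", "GPModel", function(object) {
  cat("GPModel (", object@kernel@kind, " kernel, ",
      nTraining(object), " training points)\n", sep = "")
  cat("  noise sigma^2 =", signif(object@noise, 4),
      "| prior mean =", signif(object@priorMean, 6), "\n")
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata),
        vapply(object@metadata, function(x) paste(format(x), collapse = " "),
               character(1)), sep = "=", collapse = ", "), "\n")
  }
})

# ---------------------------------------------------------------------------
# TransitionChargeSet
# ---------------------------------------------------------------------------

#' Atom-centered transition charges for one chromophore state
#'
#' TrEsp-style point charges that reproduce a transition density's
#' electrostatic potential, with the multiplicative environment scaling gamma.
#'
#' @slot charges numeric, e, one per QM atom.
#' @slot gamma unitless environment scaling, > 0.
#' @slot stateLabel string.
#' @exportClass TransitionChargeSet
setClass("TransitionChargeSet",
  representation(charges = "numeric", gamma = "numeric",
                 stateLabel = "character"))

setValidity("TransitionChargeSet", function(object) {
  if (!all(is.finite(object@charges))) return("charges must be finite")
  if (length(object@gamma) != 1 || object@gamma <= 0) {
    return("gamma must be a single value > 0")
  }
  TRUE
})

#' Construct a TransitionChargeSet
#'
#' @param charges numeric per-atom transition charges (e).
#' @param gamma unitless environment scaling factor (> 0), stored with the
#'   set; see [scaleCharges()].
#' @param stateLabel string naming the electronic state.
#' @param neutralize logical; subtract the mean so charges sum to zero
#'   (transition densities carry no monopole).
#' @return A [TransitionChargeSet-class].
#' @export
TransitionChargeSet <- function(charges, gamma = 1, stateLabel = "Qy",
                                neutralize = FALSE) {
  charges <- as.numeric(charges)
  if (neutralize && length(charges)) charges <- charges - mean(charges)
  new("TransitionChargeSet", charges = charges, gamma = as.numeric(gamma),
      stateLabel = as.character(stateLabel))
}

#' @describeIn TransitionChargeSet-class charge accessor (e)
#' @param object a TransitionChargeSet
#' @export
transitionCharges <- function(object) object@charges

setMethod("show", "TransitionChargeSet", function(object) {
  cat("TransitionChargeSet<", object@stateLabel, ">: ",
      length(object@charges), " charges, gamma = ", object@gamma,
      ", sum = ", signif(sum(object@charges), 3), " e\n", sep = "")
})

# ---------------------------------------------------------------------------
# ExcitonHamiltonian
# ---------------------------------------------------------------------------

#' Frenkel exciton Hamiltonian
#'
#' Symmetric matrix in eV whose diagonal holds site energies (one localized
#' excitation per chromophore) and whose off-diagonal holds excitonic
#' couplings.
#'
#' @slot matrix symmetric N x N numeric matrix, eV.
#' @slot siteLabels character pigment ids.
#' @slot provenance named list (frame id, model versions, ...).
#' @exportClass ExcitonHamiltonian
setClass("ExcitonHamiltonian",
  representation(matrix = "matrix", siteLabels = "character",
                 provenance = "list"))

setValidity("ExcitonHamiltonian", function(object) {
  H <- object@matrix
  if (nrow(H) != ncol(H)) return("matrix must be square")
  if (length(object@siteLabels) != nrow(H)) {
    return("one site label per row required")
  }
  if (nrow(H) > 0 && max(abs(H - t(H))) > 1e-12) {
    return("matrix must be symmetric to 1e-12")
  }
  TRUE
})

#' @describeIn ExcitonHamiltonian-class the matrix itself (eV)
#' @param object an ExcitonHamiltonian
#' @export
hamiltonianMatrix <- function(object) {
  m <- object@matrix
  dimnames(m) <- list(object@siteLabels, object@siteLabels)
  m
}

#' @describeIn ExcitonHamiltonian-class site energies (diagonal, eV)
#' @export
siteEnergies <- function(object) {
  stats::setNames(diag(object@matrix), object@siteLabels)
}

#' @describeIn ExcitonHamiltonian-class site label accessor
#' @export
siteLabels <- function(object) object@siteLabels

setMethod("show", "ExcitonHamiltonian", function(object) {
  n <- nrow(object@matrix)
  cat("ExcitonHamiltonian:", n, "sites\n")
  if (n) {
    cat("  site energies (eV):",
        paste(signif(diag(object@matrix), 6), collapse = ", "), "\n")
  }
})

# ---------------------------------------------------------------------------
# SiteEnergyPrediction
# ---------------------------------------------------------------------------

#' A predicted site energy with its decomposition
#'
#' The total is the sum of the vacuum, electrochromic-shift and polarization
#' components; the variance combines the two GP variances assuming
#' independence.
#'
#' @slot value total predicted site energy, eV.
#' @slot variance predictive variance, eV^2 (>= 0).
#' @slot components named numeric (vac, shift, pol), eV.
#' @slot pigmentId label.
#' @exportClass SiteEnergyPrediction
setClass("SiteEnergyPrediction",
  representation(value = "numeric", variance = "numeric",
                 components = "numeric", pigmentId = "character"))

setValidity("SiteEnergyPrediction", function(object) {
  if (!all(c("vac", "shift", "pol") %in% names(object@components))) {
    return("components must be named vac, shift, pol")
  }
  if (abs(object@value - sum(object@components)) > 1e-9) {
    return("value must equal the sum of components")
  }
  if (object@variance < 0) return("variance must be >= 0")
  TRUE
})

setMethod("show", "SiteEnergyPrediction", function(object) {
  cat(sprintf(
    "SiteEnergyPrediction [%s]: %.6f eV (vac %.6f + shift %.6f + pol %.6f), sd %.4g eV\n",
    object@pigmentId, object@value, object@components["vac"],
    object@components["shift"], object@components["pol"],
    sqrt(object@variance)))
})
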