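# Frenkel exciton Hamiltonians: assembly from site energies and couplings,
# diagonalization, per-residue influence analysis, and Gaussian-broadened
# stick spectra.

#' Assemble a Frenkel exciton Hamiltonian
#'
#' Diagonal = site energies (one localized excitation per chromophore),
#' off-diagonal = excitonic couplings.  Pairs absent from the coupling table
#' default to 0 with a warning; a pair listed twice with inconsistent values
#' is an error.
#'
#' @param sitePredictions named numeric vector of site energies (eV), or a
#'   list of [SiteEnergyPrediction-class] objects.
#' @param couplingTable data.frame with columns \code{i}, \code{j} (site
#'   labels or indices) and \code{V} (eV); may be NULL for no couplings.
#' @param provenance named list stored with the Hamiltonian.
#' @return An [ExcitonHamiltonian-class].
#' @export
buildHamiltonian <- function(sitePredictions, couplingTable = NULL,
                             provenance = list()) {
  if (is.list(sitePredictions) && !is.data.frame(sitePredictions) &&
      length(sitePredictions) && is(sitePredictions[[1]],
                                    "SiteEnergyPrediction")) {
    eps <- vapply(sitePredictions, function(p) p@value, numeric(1))
    names(eps) <- vapply(sitePredictions, function(p) p@pigmentId,
                         character(1))
    sitePredictions <- eps
  }
  eps <- as.numeric(sitePredictions)
  labels <- names(sitePredictions) %||% as.character(seq_along(eps))
  n <- length(eps)
  H <- diag(eps, n)
  seen <- character(0)
  if (!is.null(couplingTable) && nrow(couplingTable)) {
    for (r in seq_len(nrow(couplingTable))) {
      i <- couplingTable$i[r]; j <- couplingTable$j[r]
      ii <- if (is.numeric(i)) as.integer(i) else match(as.character(i), labels)
      jj <- if (is.numeric(j)) as.integer(j) else match(as.character(j), labels)
      if (is.na(ii) || is.na(jj) || ii == jj) {
        stop("invalid coupling pair at row ", r)
      }
      key <- paste(sort(c(ii, jj)), collapse = "-")
      v <- couplingTable$V[r]
      if (key %in% seen && abs(H[ii, jj] - v) > 1e-12) {
        stop("duplicate pair ", key, " with inconsistent coupling values")
      }
      H[ii, jj] <- v; H[jj, ii] <- v
      seen <- c(seen, key)
    }
  }
  nPairs <- n * (n - 1) / 2
  if (!is.null(couplingTable) && length(unique(seen)) < nPairs) {
    warning(nPairs - length(unique(seen)),
            " pigment pair(s) missing from the coupling table; set to 0")
  }
  new("ExcitonHamiltonian", matrix = H, siteLabels = labels,
      provenance = provenance)
}

#' Diagonalize an exciton Hamiltonian
#'
#' @param H an [ExcitonHamiltonian-class] or symmetric numeric matrix.
#' @return List with \code{energies} (ascending, eV) and
#'   \code{coefficients}: orthonormal eigenvectors as columns (site
#'   amplitudes of each exciton state).
#' @export
diagonalizeHamiltonian <- function(H) {
  m <- if (is(H, "ExcitonHamiltonian")) H@matrix else as.matrix(H)
  e <- eigen(m, symmetric = TRUE)
  ord <- order(e$values)
  list(energies = e$values[ord],
       coefficients = e$vectors[, ord, drop = FALSE])
}

#' Influence of one residue on a pigment's electrochromic shift
#'
#' eps_{P:R} = eps_shift(R on) - eps_shift(R off): the shift is predicted
#' twice, once with the full environment and once with the residue's charges
#' zeroed (its atoms are kept, so the cutoff selection is unchanged), and the
#' difference is returned.
#'
#' @param shiftModel a shift [GPModel-class].
#' @param geom a [ChromophoreGeometry-class].
#' @param env an [EnvironmentModel-class] containing the residue.
#' @param residueId integer id of the residue to probe.
#' @return Influence in eV.
#' @export
residueInfluence <- function(shiftModel, geom, env, residueId) {
  on <- predictShift(shiftModel, geom, env, computeVariance = FALSE)$mean
  off <- predictShift(shiftModel, geom, zeroResidueCharges(env, residueId),
                      computeVariance = FALSE)$mean
  on - off
}

#' Residue-influence scan over an ensemble of frames
#'
#' For one pigment, computes eps_{P:R} for every residue with at least one
#' atom within \code{radiusA} of the pigment (minimum atom-atom distance) in
#' any frame, across all frames, and summarizes per-residue mean and
#' standard deviation.
#'
#' @param shiftModel a shift [GPModel-class].
#' @param geoms list of [ChromophoreGeometry-class], one per frame.
#' @param envs list of [EnvironmentModel-class], paired with \code{geoms}.
#' @param radiusA selection radius in Angstrom (default 6).
#' @param pigmentId label for the output.
#' @return data.frame with columns pigmentId, residueId, residueName, n,
#'   meanInfluence, sdInfluence (eV), plus attribute \code{samples}: the
#'   per-frame influence matrix (frames x residues).
#' @export
residueInfluenceScan <- function(shiftModel, geoms, envs, radiusA = 6,
                                 pigmentId = "pigment") {
  stopifnot(length(geoms) == length(envs), length(geoms) >= 1)
  selected <- integer(0)
  for (k in seq_along(geoms)) {
    env <- envs[[k]]
    if (nSites(env) == 0) next
    d <- crossDist(coordinates(canonicalizeGeometry(geoms[[k]])),
                   env@positions)
    minByAtom <- apply(d, 2, min)
    resMin <- tapply(minByAtom, env@residueIds, min)
    selected <- union(selected,
                      as.integer(names(resMin)[resMin <= radiusA]))
  }
  selected <- sort(selected)
  samples <- matrix(NA_real_, length(geoms), length(selected),
                    dimnames = list(NULL, as.character(selected)))
  resNames <- character(length(selected))
  for (k in seq_along(geoms)) {
    env <- envs[[k]]
    for (ri in seq_along(selected)) {
      id <- selected[ri]
      if (!(id %in% env@residueIds)) next
      samples[k, ri] <- residueInfluence(shiftModel, geoms[[k]], env, id)
      resNames[ri] <- env@residueNames[match(id, env@residueIds)]
    }
  }
  out <- data.frame(
    pigmentId = pigmentId,
    residueId = selected,
    residueName = resNames,
    n = colSums(!is.na(samples)),
    meanInfluence = colMeans(samples, na.rm = TRUE),
    sdInfluence = apply(samples, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) > 1) stats::sd(x) else 0
    }),
    row.names = NULL)
  attr(out, "samples") <- samples
  out
}

#' Transition dipole of a chromophore from its transition charges
#'
#' mu = sum_i q_i r_i (e Angstrom); origin-independent for a neutral set.
#'
#' @param qtr a [TransitionChargeSet-class] or numeric charges.
#' @param geom a [ChromophoreGeometry-class] or coordinate matrix.
#' @return Length-3 numeric dipole vector, e Angstrom.
#' @export
transitionDipole <- function(qtr, geom) {
  if (is(qtr, "TransitionChargeSet")) qtr <- transitionCharges(qtr)
  pos <- if (is(geom, "ChromophoreGeometry")) coordinates(geom)
         else as.matrix(geom)
  as.numeric(crossprod(pos, qtr))
}

#' Gaussian-broadened stick absorption spectrum of an ensemble
#'
#' Each Hamiltonian is diagonalized; exciton transition dipoles are the
#' coefficient-weighted sums of site dipoles, each stick carries intensity
#' |mu_exciton|^2, and sticks are broadened with unit-area Gaussians of the
#' given FWHM and averaged over the ensemble.  The integrated intensity
#' therefore equals the ensemble-average total dipole strength (sum rule).
#'
#' @param hams list of [ExcitonHamiltonian-class] (the ensemble).
#' @param siteDipoles list (one per Hamiltonian) or a single N x 3 matrix of
#'   site transition dipoles, e Angstrom.
#' @param fwhm Gaussian full width at half maximum, eV.
#' @param energyGrid numeric grid (eV); default spans the exciton energies
#'   with a 1 meV spacing and 5 FWHM of margin.
#' @return data.frame with columns \code{energy} (eV) and \code{intensity}
#'   (dipole-strength density per eV).
#' @export
broadenedSpectrum <- function(hams, siteDipoles, fwhm = 0.02,
                              energyGrid = NULL) {
  if (is(hams, "ExcitonHamiltonian")) hams <- list(hams)
  if (is.matrix(siteDipoles)) {
    siteDipoles <- rep(list(siteDipoles), length(hams))
  }
  stopifnot(length(siteDipoles) == length(hams), fwhm > 0)
  sticks <- do.call(rbind, mapply(function(H, D) {
    D <- as.matrix(D)
    eig <- diagonalizeHamiltonian(H)
    muEx <- crossprod(eig$coefficients, D)      # nStates x 3
    data.frame(energy = eig$energies, strength = rowSums(muEx^2))
  }, hams, siteDipoles, SIMPLIFY = FALSE))
  if (is.null(energyGrid)) {
    lo <- min(sticks$energy) - 5 * fwhm
    hi <- max(sticks$energy) + 5 * fwhm
    energyGrid <- seq(lo, hi, by = 0.001)
  }
  sd <- fwhm / (2 * sqrt(2 * log(2)))
  intensity <- numeric(length(energyGrid))
  for (r in seq_len(nrow(sticks))) {
    if (sticks$strength[r] == 0) next
    intensity <- intensity + sticks$strength[r] *
      stats::dnorm(energyGrid, sticks$energy[r], sd)
  }
  data.frame(energy = energyGrid, intensity = intensity / length(hams))
}
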