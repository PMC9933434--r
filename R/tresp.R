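# Transition charges and polarization: Ridge-regression charge prediction
# from Coulomb-matrix descriptors, gamma environment scaling, TrEsp Coulomb
# couplings, the mutual-polarization induced-dipole solver, the polarization
# contribution to site energies, and the polarizable screening of couplings.

.MIN_DIPOLE_DIST <- 1.0  # Angstrom; hard guard against polarization catastrophe

#' Fit the linear transition-charge model
#'
#' Per-atom ridge regression from the Coulomb-matrix descriptor to the atomic
#' transition charges: q_hat_i(cm) = b_i + w_i' cm, fit jointly for all atoms
#' with penalty lambda on the weights (intercept unpenalized).  With
#' lambda = 0 this is ordinary least squares.
#'
#' @param cmMatrix numeric matrix, one Coulomb-matrix descriptor per row.
#' @param targetCharges numeric matrix (samples x atoms) of reference
#'   transition charges, e; all samples must share atom count and order.
#' @param lambda ridge penalty (>= 0).
#' @param neutralize logical; shift each predicted set to zero total charge.
#' @return An object of class \code{trespModel} with a \code{predict} path
#'   via [predictTrespCharges()].
#' @export
fitTrespModel <- function(cmMatrix, targetCharges, lambda = 1e-8,
                          neutralize = TRUE) {
  cmMatrix <- as.matrix(cmMatrix)
  targetCharges <- as.matrix(targetCharges)
  if (nrow(cmMatrix) != nrow(targetCharges)) {
    stop("descriptor and charge tables disagree in sample count")
  }
  stopifnot(lambda >= 0)
  X <- cbind(1, cmMatrix)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)))      # intercept unpenalized
  XtX <- crossprod(X) + pen
  coef <- tryCatch(solve(XtX, crossprod(X, targetCharges)),
                   error = function(e) qr.solve(XtX, crossprod(X, targetCharges),
                                                tol = 1e-12))
  structure(list(coef = coef, nAtoms = ncol(targetCharges),
                 lambda = lambda, neutralize = neutralize,
                 descriptorLength = ncol(cmMatrix)),
            class = "trespModel")
}

#' Predict transition charges for a geometry
#'
#' @param model a \code{trespModel} from [fitTrespModel()].
#' @param geom a [ChromophoreGeometry-class], or a numeric Coulomb-matrix
#'   descriptor directly.
#' @param gamma environment scaling stored on the returned set.
#' @param stateLabel electronic-state label.
#' @return A [TransitionChargeSet-class] (neutralized if the model says so).
#' @export
predictTrespCharges <- function(model, geom, gamma = 1, stateLabel = "Qy") {
  cm <- if (is(geom, "ChromophoreGeometry")) as.numeric(coulombMatrix(geom))
        else as.numeric(geom)
  if (length(cm) != model$descriptorLength) {
    stop("descriptor length does not match the fitted model")
  }
  q <- as.numeric(c(1, cm) %*% model$coef)
  TransitionChargeSet(q, gamma = gamma, stateLabel = stateLabel,
                      neutralize = model$neutralize)
}

#' Scale transition charges by the environment factor gamma
#'
#' The environment's effect on the transition density is modeled as a
#' uniform scaling of the vacuum transition charges.
#'
#' @param q a [TransitionChargeSet-class].
#' @param gamma unitless factor (> 0).
#' @return A new set with every charge multiplied by gamma and gamma stored.
#' @export
scaleCharges <- function(q, gamma) {
  stopifnot(gamma > 0)
  new("TransitionChargeSet", charges = q@charges * gamma,
      gamma = as.numeric(gamma), stateLabel = q@stateLabel)
}

#' TrEsp Coulomb coupling between two chromophores
#'
#' V = k_e sum_i sum_j q_i q_j / r_ij over atoms of chromophores I and J;
#' symmetric under exchange.
#'
#' @param qI,qJ numeric transition charges (e) or
#'   [TransitionChargeSet-class] objects.
#' @param posI,posJ numeric n x 3 coordinate matrices, Angstrom.
#' @return Coupling in eV.
#' @export
coulombCoupling <- function(qI, posI, qJ, posJ) {
  if (is(qI, "TransitionChargeSet")) qI <- transitionCharges(qI)
  if (is(qJ, "TransitionChargeSet")) qJ <- transitionCharges(qJ)
  posI <- as.matrix(posI); posJ <- as.matrix(posJ)
  stopifnot(length(qI) == nrow(posI), length(qJ) == nrow(posJ))
  d <- crossDist(posI, posJ)
  if (min(d) < 1.0) {
    stop("singularity error: chromophores overlap (inter-set distance < 1 A)")
  }
  KE_EV_ANGSTROM * as.numeric(qI %*% (1 / d) %*% qJ)
}

# Field of point charges q at positions 'at' (k x 3), in e/Angstrom^2.
chargeField <- function(q, pos, at) {
  k <- nrow(at)
  E <- matrix(0, k, 3)
  for (ax in 1:3) {
    dr <- outer(at[, ax], pos[, ax], "-")        # k x n
    r <- crossDist(at, pos)
    E[, ax] <- (dr / r^3) %*% q
  }
  E
}

#' Solve the mutual-polarization induced-dipole system
#'
#' Finds dipoles mu_m = alpha_m (E_ext,m + sum_{m' != m} T_mm' mu_m') on the
#' polarizable environment sites, where E_ext is the field of the supplied
#' source charges and T is the bare point-dipole interaction tensor
#' (3 rr'/r^2 - I)/r^3.  Sites with alpha = 0 carry exactly zero dipole.
#' Solved by a direct dense factorization up to 3000 polarizable sites and by
#' fixed-point iteration (tolerance 1e-8) beyond; both routes satisfy the
#' linear system to high accuracy.
#'
#' @param env an [EnvironmentModel-class] with polarizabilities.
#' @param sourceCharges numeric charges (e) or a [TransitionChargeSet-class].
#' @param sourcePositions numeric n x 3 matrix, Angstrom.
#' @return An m x 3 matrix of induced dipoles in e Angstrom (m = number of
#'   environment atoms; zero rows where alpha = 0), with attribute
#'   \code{residual} (max-norm residual of the linear system).
#' @export
solveInducedDipoles <- function(env, sourceCharges, sourcePositions) {
  if (!isPolarizable(env)) {
    stop("environment carries no polarizabilities")
  }
  if (is(sourceCharges, "TransitionChargeSet")) {
    sourceCharges <- transitionCharges(sourceCharges)
  }
  sourcePositions <- as.matrix(sourcePositions)
  alpha <- polarizabilities(env)
  act <- which(alpha > 0)
  m <- length(act)
  dipoles <- matrix(0, nSites(env), 3)
  if (m == 0 || all(sourceCharges == 0)) {
    attr(dipoles, "residual") <- 0
    return(dipoles)
  }
  pos <- env@positions[act, , drop = FALSE]
  a <- alpha[act]
  dsrc <- crossDist(pos, sourcePositions)
  if (min(dsrc) < 0.5) {
    stop("source charge within 0.5 Angstrom of a polarizable site")
  }
  E <- chargeField(sourceCharges, sourcePositions, pos)

  if (m == 1) {
    dipoles[act, ] <- a * E
    attr(dipoles, "residual") <- 0
    return(dipoles)
  }
  dss <- crossDist(pos, pos)
  if (min(dss[upper.tri(dss)]) < .MIN_DIPOLE_DIST) {
    stop("polarization catastrophe guard: polarizable sites closer than ",
         .MIN_DIPOLE_DIST, " Angstrom")
  }

  # dipole interaction tensor blocks, (3m x 3m) with zero diagonal blocks
  Tfull <- matrix(0, 3 * m, 3 * m)
  for (i in seq_len(m)) {
    ri <- pos[i, ]
    for (j in seq_len(m)) {
      if (i == j) next
      dr <- ri - pos[j, ]
      r2 <- sum(dr * dr)
      r <- sqrt(r2)
      Tij <- (3 * tcrossprod(dr) / r2 - diag(3)) / r^3
      Tfull[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] <- Tij
    }
  }
  Evec <- as.numeric(t(E))
  if (m <= 3000) {
    A <- diag(rep(1 / a, each = 3)) - Tfull
    mu <- solve(A, Evec)
  } else {
    mu <- rep(a, each = 3) * Evec
    for (iter in 1:500) {
      muNew <- rep(a, each = 3) * (Evec + as.numeric(Tfull %*% mu))
      if (max(abs(muNew - mu)) < 1e-8) { mu <- muNew; break }
      mu <- muNew
      if (iter == 500) stop("induced-dipole iteration did not converge")
    }
  }
  res <- max(abs(mu / rep(a, each = 3) - Tfull %*% mu - Evec))
  dipoles[act, ] <- matrix(mu, ncol = 3, byrow = TRUE)
  attr(dipoles, "residual") <- res
  dipoles
}

# Interaction -k_e * sum_m mu_m . E_m(q at pos), eV; shared by the
# polarization and screening terms.
dipoleFieldInteraction <- function(dipoles, env, q, pos) {
  act <- which(rowSums(abs(dipoles)) > 0)
  if (!length(act)) return(0)
  E <- chargeField(q, pos, env@positions[act, , drop = FALSE])
  -KE_EV_ANGSTROM * sum(dipoles[act, , drop = FALSE] * E)
}

#' Polarization contribution to a site energy
#'
#' The resonant response of the polarizable environment to the transition
#' density, approximated by transition charges: the dipoles induced by the
#' transition charges interact with their own inducing field,
#' eps_pol = prefactor * k_e * sum_m mu_m . E_m, with the linear-response
#' self-energy prefactor -1/2 by default.  Non-positive for any non-zero
#' transition field (negative-semidefinite quadratic form in the charges).
#'
#' @param qtr a [TransitionChargeSet-class] (scaled by its gamma already if
#'   desired) or numeric charges, e.
#' @param geom the chromophore [ChromophoreGeometry-class].
#' @param env a polarizable [EnvironmentModel-class].
#' @param prefactor energy prefactor on the dipole-field interaction;
#'   default -1/2 (induction work included).
#' @return eps_pol in eV (<= 0 for the default prefactor).
#' @export
polarizationSiteContribution <- function(qtr, geom, env, prefactor = -0.5) {
  if (!isPolarizable(env)) stop("environment carries no polarizabilities")
  if (is(qtr, "TransitionChargeSet")) qtr <- transitionCharges(qtr)
  geom <- canonicalizeGeometry(geom)
  stopifnot(length(qtr) == nAtoms(geom))
  if (all(qtr == 0)) return(0)
  pos <- coordinates(geom)
  mu <- solveInducedDipoles(env, qtr, pos)
  # dipoleFieldInteraction returns -k_e sum mu.E; scale to prefactor * k_e sum
  (-prefactor) * dipoleFieldInteraction(mu, env, qtr, pos)
}

#' Polarizable screening contribution to a coupling
#'
#' The environment screens the Coulomb coupling: the dipoles induced by the
#' transition charges of chromophore J interact with the field generated by
#' the transition charges of chromophore I,
#' V_screen = prefactor * k_e * sum_m mu_m({q}_J) . E_m({q}_I), prefactor -1
#' by default.  Symmetric under I <-> J exchange to numerical tolerance, and
#' typically opposite in sign to the bare Coulomb coupling (screening).
#'
#' @param qI,qJ transition charges of the two chromophores (numeric or
#'   [TransitionChargeSet-class]).
#' @param posI,posJ coordinate matrices, Angstrom.
#' @param env a polarizable [EnvironmentModel-class].
#' @param prefactor energy prefactor, default -1.
#' @return Screening term in eV.
#' @export
screeningTerm <- function(qI, posI, qJ, posJ, env, prefactor = -1) {
  if (!isPolarizable(env)) return(0)
  if (all(polarizabilities(env) == 0)) return(0)
  if (is(qI, "TransitionChargeSet")) qI <- transitionCharges(qI)
  if (is(qJ, "TransitionChargeSet")) qJ <- transitionCharges(qJ)
  posI <- as.matrix(posI); posJ <- as.matrix(posJ)
  muJ <- solveInducedDipoles(env, qJ, posJ)
  # V = prefactor * k_e * sum(mu.E) = (-prefactor) * (-k_e sum(mu.E))
  (-prefactor) * dipoleFieldInteraction(muJ, env, qI, posI)
}
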