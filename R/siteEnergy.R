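# Sequential site-energy predictors: epsilon_hat = eps_vac + eps_shift
# (+ eps_pol).  One model per pigment type; vacuum model on Coulomb-matrix
# descriptors with mean-of-targets prior, shift model on (CM, potential)
# bundles with a zero prior mean and the composite kernel, so the predicted
# shift for an isolated pigment is exactly zero.

# Build (cm) bundles for a list of geometries, checking the single-type rule.
vacuumBundles <- function(geoms) {
  types <- vapply(geoms, pigmentType, character(1))
  if (length(unique(types)) != 1) {
    stop("mixed pigment types (", paste(unique(types), collapse = ", "),
         "): train one model per pigment type")
  }
  lapply(geoms, function(g) list(cm = as.numeric(coulombMatrix(g))))
}

shiftBundles <- function(geoms, envs, cutoffA) {
  if (length(geoms) != length(envs)) {
    stop("geometry/environment count mismatch")
  }
  types <- vapply(geoms, pigmentType, character(1))
  if (length(unique(types)) != 1) {
    stop("mixed pigment types: train one model per pigment type")
  }
  mapply(function(g, e) {
    list(cm = as.numeric(coulombMatrix(g)),
         pot = mmPotential(g, e, cutoffA))
  }, geoms, envs, SIMPLIFY = FALSE)
}

#' Train the vacuum site-energy model
#'
#' Gaussian process on hydrogen-free Coulomb-matrix descriptors with a Matern
#' (nu = 5/2) kernel and prior mean equal to the average of the training
#' energies.  Hyperparameters (amplitude, lengthscale, noise) are set by
#' maximizing the log marginal likelihood.
#'
#' @param geoms list of [ChromophoreGeometry-class], one pigment type.
#' @param targets vacuum excitation energies, eV (>= 10 samples).
#' @param config a run configuration, see [defaultRunConfig()]; uses
#'   \code{restarts}, \code{seed} and \code{kernelBounds}.
#' @return A [GPModel-class] with metadata target = "eps_vac".
#' @export
trainVacuumModel <- function(geoms, targets, config = defaultRunConfig()) {
  stopifnot(length(geoms) >= 10, length(targets) == length(geoms))
  X <- vacuumBundles(geoms)
  opt <- optimizeHyperparameters(X, targets, "matern",
                                 bounds = config$kernelBounds %||% list(),
                                 restarts = config$restarts %||% 5,
                                 seed = config$seed %||% 1,
                                 priorMean = "mean_of_targets")
  fitGP(X, targets, opt$kernel, noise = opt$noise,
        priorMean = "mean_of_targets",
        metadata = list(pigmentType = pigmentType(geoms[[1]]),
                        target = "eps_vac", logML = opt$logML))
}

#' Train the electrochromic-shift model
#'
#' Gaussian process on paired (Coulomb matrix, MM potential) bundles with the
#' composite kernel of [compositeShiftKernel()] and a zero prior mean.
#'
#' @param geoms list of [ChromophoreGeometry-class].
#' @param envs list of [EnvironmentModel-class], paired with \code{geoms}.
#' @param targets electrochromic shifts eps_QM/MM - eps_vac, eV.
#' @param config run configuration; uses \code{cutoffA}, \code{restarts},
#'   \code{seed}, \code{kernelBounds}, and optionally
#'   \code{kernelKind = "linear"} to fit the pure linear-response model.
#' @return A [GPModel-class] with metadata target = "eps_shift" and the
#'   cutoff used to build the potential descriptors.
#' @export
trainShiftModel <- function(geoms, envs, targets,
                            config = defaultRunConfig()) {
  cutoffA <- config$cutoffA %||% 30
  kind <- config$kernelKind %||% "composite_shift"
  stopifnot(kind %in% c("composite_shift", "linear"))
  X <- shiftBundles(geoms, envs, cutoffA)
  opt <- optimizeHyperparameters(X, targets, kind,
                                 bounds = config$kernelBounds %||% list(),
                                 restarts = config$restarts %||% 5,
                                 seed = config$seed %||% 1,
                                 priorMean = "zero")
  fitGP(X, targets, opt$kernel, noise = opt$noise, priorMean = "zero",
        metadata = list(pigmentType = pigmentType(geoms[[1]]),
                        target = "eps_shift", cutoffA = cutoffA,
                        logML = opt$logML))
}

#' Predict the shift for one geometry/environment pair
#'
#' @param model a shift [GPModel-class] (from [trainShiftModel()]).
#' @param geom a [ChromophoreGeometry-class].
#' @param env an [EnvironmentModel-class].
#' @param computeVariance logical.
#' @return List with \code{mean} and \code{variance} (eV, eV^2).
#' @export
predictShift <- function(model, geom, env, computeVariance = TRUE) {
  cutoffA <- model@metadata$cutoffA %||% 30
  b <- list(cm = as.numeric(coulombMatrix(geom)),
            pot = mmPotential(geom, env, cutoffA))
  p <- predictGP(model, b, computeVariance = computeVariance)
  list(mean = p$mean[1], variance = p$variance[1])
}

#' Sequential site-energy prediction
#'
#' eps_hat = eps_hat_vac + eps_hat_shift + eps_hat_pol: the three components
#' are computed independently and summed.  The polarization component is 0
#' when no polarization context is supplied; otherwise it is evaluated
#' analytically from the context's transition charges and the environment's
#' polarizabilities (see [polarizationSiteContribution()]).  The predictive
#' variance is the sum of the two GP variances (independence assumed).
#'
#' @param vacModel vacuum [GPModel-class].
#' @param shiftModel shift [GPModel-class].
#' @param geom a [ChromophoreGeometry-class].
#' @param env an [EnvironmentModel-class].
#' @param polContext NULL, or a list with element \code{charges} (a
#'   [TransitionChargeSet-class]); used only when the environment carries
#'   polarizabilities.
#' @param pigmentId label stored on the prediction.
#' @return A [SiteEnergyPrediction-class].
#' @export
predictSiteEnergy <- function(vacModel, shiftModel, geom, env,
                              polContext = NULL, pigmentId = "pigment") {
  bv <- list(cm = as.numeric(coulombMatrix(geom)))
  pv <- predictGP(vacModel, bv)
  ps <- predictShift(shiftModel, geom, env)
  pol <- 0
  if (!is.null(polContext) && isPolarizable(env) &&
      any(polarizabilities(env) > 0)) {
    pol <- polarizationSiteContribution(polContext$charges, geom, env,
                                        prefactor = polContext$prefactor
                                        %||% -0.5)
  }
  comps <- c(vac = pv$mean[1], shift = ps$mean, pol = pol)
  new("SiteEnergyPrediction", value = sum(comps),
      variance = pv$variance[1] + ps$variance,
      components = comps, pigmentId = as.character(pigmentId))
}

#' Charge-density-coupling (CDC) electrochromic shift
#'
#' The null model: fixed difference-density charges dq on the QM atoms
#' interact bare with the environment charges,
#' eps_shift = k_e sum_i sum_m dq_i q_m / r_im, over the residues retained by
#' the same cutoff rule as [mmPotential()].  No dielectric screening factor.
#'
#' @param deltaQ numeric difference-density charges, e, one per QM atom.
#' @param geom a [ChromophoreGeometry-class].
#' @param env an [EnvironmentModel-class].
#' @param cutoffA residue-inclusion cutoff, Angstrom.
#' @return Electrochromic shift in eV.
#' @examples
#' g <- ChromophoreGeometry("X1", "C", rbind(c(0, 0, 0)), "ONE")
#' e <- EnvironmentModel(rbind(c(5, 0, 0)), -1, 1L)
#' cdcShift(0.1, g, e)  # 14.3996454 * 0.1 * (-1) / 5
#' @export
cdcShift <- function(deltaQ, geom, env, cutoffA = 30) {
  geom <- canonicalizeGeometry(geom)
  if (length(deltaQ) != nAtoms(geom)) {
    stop("one difference-density charge per QM atom required")
  }
  if (!all(is.finite(deltaQ))) stop("difference-density charges must be finite")
  KE_EV_ANGSTROM * sum(deltaQ * mmPotential(geom, env, cutoffA))
}
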