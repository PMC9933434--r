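# Exact Gaussian-process regression: Cholesky-based fitting, posterior
# mean/variance prediction, log marginal likelihood, and multi-start
# hyperparameter optimization.

.GP_JITTER <- 1e-10
.MODEL_SCHEMA_VERSION <- 1L

# Stack raw inputs into descriptor bundles.  Accepts a list of bundles
# already, or builds matern bundles from a numeric matrix (rows = samples).
asBundles <- function(X) {
  if (is.matrix(X)) X <- lapply(seq_len(nrow(X)), function(i) list(cm = X[i, ]))
  if (!is.list(X)) stop("X must be a list of descriptor bundles or a matrix")
  X
}

# Cholesky of K + (noise + jitter) I with an actionable error message.
regularizedChol <- function(K, noise) {
  Kr <- K + diag(noise + .GP_JITTER, nrow(K))
  out <- tryCatch(chol(Kr), error = function(e) e)
  if (inherits(out, "error")) {
    stop("Gram matrix is numerically singular (duplicated inputs with ",
         "noise sigma^2 = 0?); add observation noise or jitter", call. = FALSE)
  }
  out
}

#' Fit an exact Gaussian-process regression model
#'
#' Solves (K + sigma^2 I) alpha = y - mu with K_ij = kappa(x_i, x_j), storing
#' the coefficients and the Cholesky factor for later predictions.  A fixed
#' jitter of 1e-10 is added to the diagonal before factorization.
#'
#' @param X list of descriptor bundles (named lists with \code{cm} and/or
#'   \code{pot}), or a numeric matrix of row-descriptors for a Matern kernel.
#' @param y numeric targets (eV for energy models).
#' @param kernel a [KernelSpec-class].
#' @param noise observation noise variance sigma^2 (>= 0).
#' @param priorMean "mean_of_targets" (vacuum model convention) or "zero"
#'   (shift model convention, required for the exact zero-shift constraint).
#' @param metadata named list stored with the model (pigmentType, target, ...).
#' @return A [GPModel-class].
#' @export
fitGP <- function(X, y, kernel, noise = 0,
                  priorMean = c("mean_of_targets", "zero"),
                  metadata = list()) {
  X <- asBundles(X)
  priorMean <- match.arg(priorMean)
  stopifnot(length(X) >= 1, length(y) == length(X), noise >= 0)
  mu <- if (priorMean == "mean_of_targets") mean(y) else 0
  if (noise == 0) {
    flat <- do.call(rbind, lapply(X, function(b)
      c(b$cm %||% numeric(0), b$pot %||% numeric(0))))
    if (anyDuplicated(flat)) {
      stop("duplicated training inputs with noise sigma^2 = 0 make the ",
           "kernel system singular; add observation noise or jitter",
           call. = FALSE)
    }
  }
  K <- kernelGram(kernel, X)
  L <- regularizedChol(K, noise)
  alpha <- backsolve(L, forwardsolve(t(L), y - mu))
  metadata$schemaVersion <- .MODEL_SCHEMA_VERSION
  metadata$priorMeanMode <- priorMean
  new("GPModel", kernel = kernel, noise = noise, trainX = X,
      alpha = as.numeric(alpha), priorMean = mu, cholK = L,
      metadata = metadata)
}

#' Posterior mean and variance of a fitted GP
#'
#' mean(x*) = mu + sum_m kappa(x*, x_m) alpha_m;
#' var(x*) = kappa(x*, x*) - k*' (K + sigma^2 I)^{-1} k*, clipped at 0.
#'
#' @param model a [GPModel-class].
#' @param Xstar a single descriptor bundle, a list of bundles, or a matrix of
#'   row-descriptors.
#' @param computeVariance logical; skip the variance solve when FALSE.
#' @return List with numeric \code{mean} and \code{variance} (NA when not
#'   computed), one entry per test point.
#' @export
predictGP <- function(model, Xstar, computeVariance = TRUE) {
  if (is.list(Xstar) && !is.null(names(Xstar)) &&
      any(c("cm", "pot") %in% names(Xstar))) {
    Xstar <- list(Xstar)
  }
  Xstar <- asBundles(Xstar)
  checkShape <- function(b) {
    ref <- model@trainX[[1]]
    for (f in c("cm", "pot")) {
      if (!is.null(ref[[f]]) &&
          (is.null(b[[f]]) || length(b[[f]]) != length(ref[[f]]))) {
        stop("descriptor '", f, "' missing or of different length than ",
             "the training inputs")
      }
    }
  }
  lapply(Xstar, checkShape)
  Ks <- kernelGram(model@kernel, Xstar, model@trainX)  # ntest x ntrain
  mu <- model@priorMean + as.numeric(Ks %*% model@alpha)
  v <- rep(NA_real_, length(Xstar))
  if (computeVariance) {
    prior <- kernelDiag(model@kernel, Xstar)
    w <- forwardsolve(t(model@cholK), t(Ks))
    v <- pmax(prior - colSums(w * w), 0)
  }
  list(mean = mu, variance = v)
}

#' Log marginal likelihood of data under a GP prior
#'
#' -1/2 (y-mu)' (K + sigma^2 I)^{-1} (y-mu) - 1/2 log|K + sigma^2 I|
#' - n/2 log(2 pi).
#'
#' @param X descriptor bundles or matrix (as in [fitGP()]).
#' @param y numeric targets.
#' @param kernel a [KernelSpec-class].
#' @param noise observation noise variance.
#' @param priorMean "mean_of_targets" or "zero".
#' @return Scalar log marginal likelihood.
#' @export
logMarginalLikelihood <- function(X, y, kernel, noise = 0,
                                  priorMean = c("mean_of_targets", "zero")) {
  X <- asBundles(X)
  priorMean <- match.arg(priorMean)
  mu <- if (priorMean == "mean_of_targets") mean(y) else 0
  K <- kernelGram(kernel, X)
  L <- regularizedChol(K, noise)
  r <- y - mu
  a <- forwardsolve(t(L), r)
  -0.5 * sum(a * a) - sum(log(diag(L))) - length(y) / 2 * log(2 * pi)
}

# Pack/unpack hyperparameters (including noise sd) for log-space optimization.
kernelParamNames <- function(kind) {
  switch(kind,
    matern = c("sigma", "l"),
    linear = "sigma1",
    composite_shift = c("sigma1", "sigma2", "l"),
    stop("unknown kernel kind: ", kind))
}

#' Optimize GP hyperparameters by log-marginal-likelihood maximization
#'
#' Multi-start L-BFGS-B in log-space over the kernel hyperparameters and the
#' observation noise standard deviation.  Deterministic given \code{seed}.
#' A restart whose objective is non-finite is discarded; an error is raised
#' only if every restart fails.
#'
#' @param X descriptor bundles or matrix.
#' @param y numeric targets.
#' @param kernelKind "matern", "linear" or "composite_shift".
#' @param bounds named list of length-2 numeric ranges for each hyperparameter
#'   and for \code{noise_sd}; missing entries default to c(1e-4, 1e4) times a
#'   data-driven scale.
#' @param restarts number of optimization starts (>= 1): the first is a
#'   data-driven heuristic (amplitude from the target spread, lengthscale
#'   from the median pairwise descriptor distance), the second the bounds'
#'   log-space midpoint, the rest seeded random draws.
#' @param seed integer seed for the restart draws.
#' @param priorMean passed to the likelihood.
#' @return List with \code{kernel} (a [KernelSpec-class]), \code{noise}
#'   (variance), and \code{logML} at the optimum.
#' @export
optimizeHyperparameters <- function(X, y, kernelKind, bounds = list(),
                                    restarts = 5, seed = 1,
                                    priorMean = c("mean_of_targets", "zero")) {
  X <- asBundles(X)
  priorMean <- match.arg(priorMean)
  stopifnot(restarts >= 1)
  pn <- kernelParamNames(kernelKind)
  sdY <- stats::sd(y)
  if (!is.finite(sdY) || sdY == 0) sdY <- 1
  defaultBounds <- list(
    sigma = c(1e-4, 1e2) * sdY, sigma1 = c(1e-6, 1e3),
    sigma2 = c(1e-6, 1e3), l = c(1e-2, 1e4),
    noise_sd = c(1e-6, 10) * sdY)
  allNames <- c(pn, "noise_sd")
  lo <- log(vapply(allNames, function(nm)
    (bounds[[nm]] %||% defaultBounds[[nm]])[1], numeric(1)))
  hi <- log(vapply(allNames, function(nm)
    (bounds[[nm]] %||% defaultBounds[[nm]])[2], numeric(1)))
  stopifnot(all(is.finite(lo)), all(is.finite(hi)), all(hi > lo))

  objective <- function(logTheta) {
    th <- exp(logTheta)
    ks <- do.call(KernelSpec,
                  c(list(kind = kernelKind), as.list(th[seq_along(pn)])))
    val <- tryCatch(
      -logMarginalLikelihood(X, y, ks, noise = th[length(th)]^2,
                             priorMean = priorMean),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e12 else val
  }

  # data-driven first start: amplitude from the target spread, lengthscale
  # from the median pairwise descriptor distance, small initial noise
  sub <- X[seq_len(min(length(X), 200))]
  medDist <- function(M) {
    d <- crossDist(M, M)
    stats::median(d[upper.tri(d)])
  }
  cmMat <- tryCatch(do.call(rbind, lapply(sub, function(b) b$cm)),
                    error = function(e) NULL)
  potMat <- tryCatch(do.call(rbind, lapply(sub, function(b) b$pot)),
                     error = function(e) NULL)
  heur <- c(
    sigma = sdY,
    sigma1 = if (!is.null(potMat)) {
      sdY / max(stats::median(sqrt(rowSums(potMat^2))), 1e-12)
    } else 1,
    l = if (!is.null(cmMat) && nrow(cmMat) > 1) max(medDist(cmMat), 1e-2)
        else 1,
    noise_sd = 0.05 * sdY)
  heur["sigma2"] <- heur[["sigma1"]]
  start0 <- pmin(pmax(log(heur[allNames]), lo), hi)

  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- rbind(start0, (lo + hi) / 2)
  if (restarts > 2) {
    extra <- matrix(stats::runif((restarts - 2) * length(lo)),
                    nrow = restarts - 2)
    starts <- rbind(starts, sweep(sweep(extra, 2, hi - lo, "*"), 2, lo, "+"))
  } else {
    starts <- starts[seq_len(max(restarts, 1)), , drop = FALSE]
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("hyperparameter optimization failed: non-finite log marginal ",
         "likelihood at every restart")
  }
  th <- exp(best$par)
  kernel <- do.call(KernelSpec,
                    c(list(kind = kernelKind), as.list(th[seq_along(pn)])))
  list(kernel = kernel, noise = th[length(th)]^2, logML = -best$value)
}

# ---------------------------------------------------------------------------
# Model store
# ---------------------------------------------------------------------------

#' Write a GPModel to a single file
#'
#' Single-file store with an explicit schema version; loading refuses a
#' mismatched schema rather than silently migrating.  Round-trip is exact.
#'
#' @param model a [GPModel-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeGPModel <- function(model, path) {
  payload <- list(
    store = "excitonML-gpmodel",
    schemaVersion = .MODEL_SCHEMA_VERSION,
    kernelKind = model@kernel@kind,
    kernelParams = model@kernel@params,
    noise = model@noise,
    priorMean = model@priorMean,
    trainX = model@trainX,
    alpha = model@alpha,
    cholK = model@cholK,
    metadata = model@metadata)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a GPModel written by [writeGPModel()]
#'
#' @param path file path.
#' @return A [GPModel-class] giving predictions identical to the saved model.
#' @export
readGPModel <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$store, "excitonML-gpmodel")) {
    stop("not an excitonML model store: ", path)
  }
  if (!identical(payload$schemaVersion, .MODEL_SCHEMA_VERSION)) {
    stop("model schema version ", payload$schemaVersion,
         " is incompatible with this build (expected ",
         .MODEL_SCHEMA_VERSION, ")")
  }
  new("GPModel",
      kernel = do.call(KernelSpec, c(list(kind = payload$kernelKind),
                                     as.list(payload$kernelParams))),
      noise = payload$noise, trainX = payload$trainX,
      alpha = payload$alpha, priorMean = payload$priorMean,
      cholK = payload$cholK, metadata = payload$metadata)
}
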