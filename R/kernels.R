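# Kernels.  The Matern smoothness is fixed at nu = 5/2: twice differentiable,
# the common default for smooth molecular-descriptor regression.

#' Matern covariance (nu = 5/2) of a distance
#'
#' k(d) = sigma^2 (1 + sqrt(5) d/l + 5 d^2 / (3 l^2)) exp(-sqrt(5) d/l).
#' Equals sigma^2 at d = 0, is strictly decreasing in d, and positive for
#' finite d.
#'
#' @param d nonnegative distance(s).
#' @param sigma amplitude (> 0).
#' @param l lengthscale (> 0).
#' @return Covariance value(s), same shape as \code{d}.
#' @export
maternKernel <- function(d, sigma, l) {
  stopifnot(sigma > 0, l > 0)
  if (any(d < 0)) stop("distance must be nonnegative")
  s <- sqrt(5) * d / l
  sigma^2 * (1 + s + s^2 / 3) * exp(-s)
}

#' Linear kernel on potential descriptors
#'
#' kappa_1 = sigma1^2 <phi, phi'>: the direct electrostatic interaction
#' between the QM and MM regions.  A GP with this kernel alone is equivalent
#' to (ridge-regularized) ordinary linear regression on the potential, with
#' effective QM charges given by the regression coefficients.
#'
#' @param phi,phi2 numeric potential descriptors of equal length.
#' @param sigma1 amplitude (> 0).
#' @return Scalar kernel value.
#' @export
linearKernel <- function(phi, phi2, sigma1) {
  stopifnot(sigma1 > 0)
  sigma1^2 * interactionWeight(phi, phi2)
}

#' Composite electrochromic-shift kernel
#'
#' kappa = sigma1^2 <phi, phi'> + sigma2^2 <phi, phi'> * matern(|cm - cm'|; 1, l).
#'
#' The first term is the direct (linear) QM-MM electrostatic response; the
#' second is a nonlinear response of the QM internal degrees of freedom,
#' weighted by the magnitude of the QM-MM interaction.  Both terms carry the
#' potential inner product, so the kernel (and with a zero prior mean, the
#' predicted shift) vanishes identically whenever either potential is zero:
#' an isolated pigment has exactly zero electrochromic shift by construction.
#'
#' @param x,x2 descriptor bundles: named lists with elements \code{cm}
#'   (Coulomb-matrix vector) and \code{pot} (potential vector).
#' @param sigma1,sigma2 amplitudes (> 0).
#' @param l Matern lengthscale on Coulomb-matrix distance (> 0).
#' @return Scalar kernel value.
#' @export
compositeShiftKernel <- function(x, x2, sigma1, sigma2, l) {
  if (is.null(x$cm) || is.null(x$pot) || is.null(x2$cm) || is.null(x2$pot)) {
    stop("bundle missing a 'cm' or 'pot' descriptor")
  }
  w <- interactionWeight(x$pot, x2$pot)
  if (w == 0) return(0)
  dcm <- sqrt(sum((x$cm - x2$cm)^2))
  sigma1^2 * w + sigma2^2 * w * maternKernel(dcm, 1, l)
}

# Evaluate kernel between two descriptor bundles under a KernelSpec.
evalKernel <- function(spec, x, x2) {
  p <- spec@params
  switch(spec@kind,
    matern = {
      if (is.null(x$cm) || is.null(x2$cm)) stop("bundle missing 'cm'")
      maternKernel(sqrt(sum((x$cm - x2$cm)^2)), p[["sigma"]], p[["l"]])
    },
    linear = {
      if (is.null(x$pot) || is.null(x2$pot)) stop("bundle missing 'pot'")
      linearKernel(x$pot, x2$pot, p[["sigma1"]])
    },
    composite_shift = compositeShiftKernel(x, x2, p[["sigma1"]],
                                           p[["sigma2"]], p[["l"]]))
}

# Gram matrix (or cross matrix) of kernel evaluations between bundle lists.
# Vectorized over the stacked descriptor matrices; falls back to nothing
# slower because every kernel here factors through inner products/distances.
kernelGram <- function(spec, X, X2 = NULL) {
  sym <- is.null(X2)
  if (sym) X2 <- X
  p <- spec@params
  getMat <- function(L, what) {
    do.call(rbind, lapply(L, function(b) {
      v <- b[[what]]
      if (is.null(v)) stop("bundle missing '", what, "' descriptor")
      as.numeric(v)
    }))
  }
  if (spec@kind == "matern") {
    A <- getMat(X, "cm"); B <- getMat(X2, "cm")
    K <- maternKernel(crossDist(A, B), p[["sigma"]], p[["l"]])
  } else if (spec@kind == "linear") {
    A <- getMat(X, "pot"); B <- getMat(X2, "pot")
    K <- p[["sigma1"]]^2 * tcrossprod(A, B)
  } else {
    A <- getMat(X, "pot"); B <- getMat(X2, "pot")
    W <- tcrossprod(A, B)
    Ac <- getMat(X, "cm"); Bc <- getMat(X2, "cm")
    M <- maternKernel(crossDist(Ac, Bc), 1, p[["l"]])
    K <- p[["sigma1"]]^2 * W + p[["sigma2"]]^2 * W * M
    # the potential factor makes kappa exactly 0 for zero potentials; enforce
    # exact zeros against floating-point dust from the matrix products
    K[W == 0] <- 0
  }
  if (sym) K <- (K + t(K)) / 2
  K
}

# Prior variance kappa(x, x) for each bundle in a list.
kernelDiag <- function(spec, X) {
  vapply(X, function(b) evalKernel(spec, b, b), numeric(1))
}
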