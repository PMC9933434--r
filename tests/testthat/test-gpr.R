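test_that("Matern 5/2 kernel has the right limits and a PSD Gram matrix", {
  expect_equal(maternKernel(0, sigma = 0.3, l = 2), 0.09)
  expect_lt(maternKernel(100 * 2, 1, 2), 1e-10)
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(maternKernel(d, 1, 1)) < 0))
  expect_true(all(maternKernel(d, 1, 1) > 0))
  expect_error(maternKernel(-1, 1, 1), "nonnegative")

  set.seed(20)
  X <- matrix(rnorm(20 * 4), 20)
  K <- excitonML:::kernelGram(KernelSpec("matern", sigma = 1.3, l = 0.8),
                              lapply(1:20, function(i) list(cm = X[i, ])))
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("linear kernel equals sigma1^2 <phi, phi'>", {
  expect_equal(linearKernel(c(3, 4), c(3, 4), 1), 25)
  expect_equal(linearKernel(c(1, 2), c(0, 0), 2), 0)
  expect_equal(linearKernel(c(1, -1, 2), c(2, 1, 0), 0.5), 0.25 * 1)
})

test_that("GP with linear kernel reproduces ridge-type linear regression", {
  set.seed(8)
  n <- 40; p <- 6
  Phi <- matrix(rnorm(n * p), n)
  w <- rnorm(p)
  y <- as.numeric(Phi %*% w)
  X <- lapply(seq_len(n), function(i) list(pot = Phi[i, ]))
  noise <- 1e-4
  m <- fitGP(X, y, KernelSpec("linear", sigma1 = 1), noise = noise,
             priorMean = "zero")
  star <- matrix(rnorm(5 * p), 5)
  Xs <- lapply(1:5, function(i) list(pot = star[i, ]))
  got <- predictGP(m, Xs, computeVariance = FALSE)$mean
  # closed-form ridge on the feature map: w_hat = (Phi'Phi + noise I)^-1 Phi'y
  wHat <- solve(crossprod(Phi) + diag(noise + 1e-10, p), crossprod(Phi, y))
  expect_equal(got, as.numeric(star %*% wHat), tolerance = 1e-8)
})

test_that("composite shift kernel is zero at zero potential and PSD", {
  x <- list(cm = c(1, 2, 3), pot = c(0, 0))
  y <- list(cm = c(1.5, 2, 2.5), pot = c(0.4, -0.2))
  expect_identical(compositeShiftKernel(x, y, 1, 1, 1), 0)
  expect_identical(compositeShiftKernel(y, x, 1, 1, 1), 0)
  expect_equal(compositeShiftKernel(y, y, 0.7, 1.3, 2),
               0.7^2 * sum(y$pot^2) + 1.3^2 * sum(y$pot^2))
  expect_error(compositeShiftKernel(list(cm = 1), y, 1, 1, 1), "missing")

  set.seed(31)
  bundles <- lapply(1:30, function(i)
    list(cm = rnorm(5), pot = rnorm(4)))
  K <- excitonML:::kernelGram(
    KernelSpec("composite_shift", sigma1 = 0.5, sigma2 = 1.1, l = 2),
    bundles)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
})

test_that("fitGP solves the kernel linear system", {
  # single point, sigma^2 = 0: alpha = (y - mu) / kappa(x, x)
  x1 <- list(list(cm = c(1, 2)))
  k <- KernelSpec("matern", sigma = 2, l = 1)
  m1 <- fitGP(x1, 5, k, noise = 0, priorMean = "zero")
  expect_equal(m1@alpha, 5 / 4, tolerance = 1e-8)

  # 3 points vs explicit dense inverse
  set.seed(2)
  X <- lapply(1:3, function(i) list(cm = rnorm(4)))
  y <- rnorm(3)
  m3 <- fitGP(X, y, k, noise = 0.1, priorMean = "mean_of_targets")
  K <- excitonML:::kernelGram(k, X)
  expect_equal(m3@alpha,
               as.numeric(solve(K + diag(0.1 + 1e-10, 3), y - mean(y))),
               tolerance = 1e-10)

  # constant targets with mean-of-targets prior: alpha = 0
  mC <- fitGP(X, rep(2.1, 3), k, noise = 0.01, priorMean = "mean_of_targets")
  expect_equal(mC@alpha, rep(0, 3), tolerance = 1e-12)

  # duplicated inputs at zero noise: actionable error
  Xd <- list(list(cm = c(1, 1)), list(cm = c(1, 1)))
  expect_error(fitGP(Xd, c(0, 1), k, noise = 0), "jitter|noise")
})

test_that("predictGP matches the dense posterior oracle", {
  set.seed(14)
  k <- KernelSpec("matern", sigma = 1.2, l = 1.5)
  X <- lapply(1:20, function(i) list(cm = rnorm(3)))
  y <- rnorm(20)
  noise <- 0.05
  m <- fitGP(X, y, k, noise = noise, priorMean = "mean_of_targets")
  Xs <- lapply(1:10, function(i) list(cm = rnorm(3)))
  got <- predictGP(m, Xs)
  K <- excitonML:::kernelGram(k, X)
  Ks <- excitonML:::kernelGram(k, Xs, X)
  oracle <- bfGPPosterior(K, y, noise, mean(y), Ks, rep(1.2^2, 10))
  expect_equal(got$mean, oracle$mean, tolerance = 1e-10)
  expect_equal(got$variance, oracle$variance, tolerance = 1e-10)
})

test_that("GP interpolates exactly at zero noise and recovers the prior far away", {
  set.seed(5)
  k <- KernelSpec("matern", sigma = 1, l = 1)
  X <- lapply(1:8, function(i) list(cm = runif(2, 0, 3)))
  y <- rnorm(8)
  m <- fitGP(X, y, k, noise = 0, priorMean = "mean_of_targets")
  p <- predictGP(m, X)
  expect_equal(p$mean, y, tolerance = 1e-8)
  expect_true(all(p$variance <= 1e-8))
  far <- predictGP(m, list(list(cm = c(1e4, 1e4))))
  expect_equal(far$mean, mean(y), tolerance = 1e-8)
  expect_equal(far$variance, 1, tolerance = 1e-8)
})

test_that("posterior variance lies in [0, prior variance] and predictions are order invariant", {
  set.seed(77)
  k <- KernelSpec("matern", sigma = 0.9, l = 1.2)
  X <- lapply(1:25, function(i) list(cm = rnorm(3)))
  y <- rnorm(25)
  m <- fitGP(X, y, k, noise = 0.01)
  Xs <- lapply(1:15, function(i) list(cm = rnorm(3)))
  p <- predictGP(m, Xs)
  expect_true(all(p$variance >= 0))
  expect_true(all(p$variance <= 0.9^2 + 1e-12))

  perm <- sample(25)
  m2 <- fitGP(X[perm], y[perm], k, noise = 0.01)
  p2 <- predictGP(m2, Xs, computeVariance = FALSE)
  expect_equal(p2$mean, p$mean, tolerance = 1e-10)
})

test_that("log marginal likelihood matches the dense determinant oracle", {
  set.seed(9)
  k <- KernelSpec("matern", sigma = 1.4, l = 0.9)
  X <- lapply(1:5, function(i) list(cm = rnorm(2)))
  y <- rnorm(5)
  got <- logMarginalLikelihood(X, y, k, noise = 0.2,
                               priorMean = "mean_of_targets")
  K <- excitonML:::kernelGram(k, X)
  expect_equal(got, bfLML(K, y, 0.2, mean(y)), tolerance = 1e-10)
})

test_that("hyperparameter optimization recovers the lengthscale scale and beats random draws", {
  # data generated from a Matern GP with known hyperparameters
  set.seed(123)
  n <- 200
  D <- matrix(runif(n * 2, 0, 10), n)
  X <- lapply(seq_len(n), function(i) list(cm = D[i, ]))
  trueL <- 2; trueSigma <- 1
  K <- excitonML:::kernelGram(KernelSpec("matern", sigma = trueSigma,
                                         l = trueL), X)
  y <- as.numeric(t(chol(K + diag(1e-8, n))) %*% rnorm(n))
  opt <- optimizeHyperparameters(X, y, "matern", restarts = 3, seed = 7)
  lHat <- opt$kernel@params[["l"]]
  expect_gt(lHat, trueL / 2)
  expect_lt(lHat, trueL * 2)

  # optimum LML beats 10 random hyperparameter draws
  set.seed(99)
  for (i in 1:10) {
    kr <- KernelSpec("matern", sigma = runif(1, 0.05, 5),
                     l = runif(1, 0.05, 20))
    expect_gte(opt$logML + 1e-6,
               logMarginalLikelihood(X, y, kr, noise = opt$noise))
  }

  # determinism given the seed
  opt2 <- optimizeHyperparameters(X, y, "matern", restarts = 3, seed = 7)
  expect_identical(opt$kernel@params, opt2$kernel@params)
})

test_that("model store round-trips exactly and refuses foreign schemas", {
  set.seed(3)
  X <- lapply(1:12, function(i) list(cm = rnorm(3)))
  y <- rnorm(12)
  m <- fitGP(X, y, KernelSpec("matern", sigma = 1, l = 1), noise = 0.01,
             metadata = list(pigmentType = "TOY", target = "eps_vac"))
  path <- tempfile(fileext = ".rds")
  writeGPModel(m, path)
  m2 <- readGPModel(path)
  Xs <- lapply(1:5, function(i) list(cm = rnorm(3)))
  p1 <- predictGP(m, Xs); p2 <- predictGP(m2, Xs)
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$variance, p2$variance)

  bad <- tempfile(fileext = ".rds")
  saveRDS(list(store = "excitonML-gpmodel", schemaVersion = 999L), bad)
  expect_error(readGPModel(bad), "schema version")
  saveRDS(list(foo = 1), bad)
  expect_error(readGPModel(bad), "not an excitonML")
})
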