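# Smaller-scale checks of the sequential site-energy models; the full-size
# recovery runs live in the acceptance suite.

quickCfg <- function(...) defaultRunConfig(restarts = 1, ...)

test_that("vacuum model predicts a constant when all targets are equal", {
  g <- generateChromophoreEnsemble(12, seed = 21, pigmentType = "TOY")
  m <- fitGP(cmBundles(g), rep(2.1, 12),
             KernelSpec("matern", sigma = 0.1, l = 10), noise = 1e-4,
             priorMean = "mean_of_targets")
  gNew <- generateChromophoreEnsemble(5, seed = 22, pigmentType = "TOY")
  p <- predictGP(m, cmBundles(gNew), computeVariance = FALSE)
  expect_equal(p$mean, rep(2.1, 5), tolerance = 1e-9)
})

test_that("vacuum training rejects mixed pigment types and short inputs", {
  gA <- generateChromophoreEnsemble(6, seed = 1, pigmentType = "TOY")
  gB <- generateChromophoreEnsemble(6, seed = 1, nHeavy = 13,
                                    pigmentType = "TOY13")
  expect_error(trainVacuumModel(c(gA, gB), rnorm(12), quickCfg()),
               "pigment type")
  expect_error(trainVacuumModel(gA[1:5], rnorm(5), quickCfg()))
})

test_that("vacuum model trained on shuffled samples gives identical predictions", {
  spec <- defaultOracleSpec(noiseSd = 0)
  d <- generateBenchmarkData(40, spec, seed = 13)
  cfg <- quickCfg()
  m1 <- trainVacuumModel(d$geoms, d$epsVac, cfg)
  perm <- sample(40)
  m2 <- trainVacuumModel(d$geoms[perm], d$epsVac[perm], cfg)
  gNew <- generateChromophoreEnsemble(6, seed = 99, pigmentType = "TOY")
  p1 <- predictGP(m1, cmBundles(gNew), computeVariance = FALSE)$mean
  p2 <- predictGP(m2, cmBundles(gNew), computeVariance = FALSE)$mean
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("shift model with all-zero targets predicts ~0 and empty env exactly 0", {
  d <- generateBenchmarkData(25, defaultOracleSpec(noiseSd = 0), seed = 31)
  m <- fitGP(dataBundles(d), rep(0, 25),
             KernelSpec("composite_shift", sigma1 = 0.1, sigma2 = 0.1,
                        l = 5),
             noise = 1e-6, priorMean = "zero",
             metadata = list(cutoffA = 30))
  p <- shiftPredictions(m, d)
  expect_equal(p, rep(0, 25), tolerance = 1e-8)
  # empty environment: exact zero, by construction, for every geometry
  for (g in d$geoms[1:5]) {
    expect_identical(
      predictShift(m, g, emptyEnvironment(), computeVariance = FALSE)$mean,
      0)
  }
})

test_that("pure-linear shift model is additive over disjoint environments", {
  specL <- defaultOracleSpec(geometryCoupling = 0, noiseSd = 0)
  d <- generateBenchmarkData(40, specL, seed = 41)
  m <- trainShiftModel(d$geoms, d$envs, d$epsShift,
                       quickCfg(kernelKind = "linear"))
  g <- d$geoms[[1]]
  envA <- randomEnvironment(2, 3, seed = 7)
  envB <- randomEnvironment(2, 3, seed = 8)
  both <- EnvironmentModel(rbind(envA@positions, envB@positions),
                           c(charges(envA), charges(envB)),
                           c(residueIds(envA), residueIds(envB) + 10L))
  pA <- predictShift(m, g, envA, computeVariance = FALSE)$mean
  pB <- predictShift(m, g, envB, computeVariance = FALSE)$mean
  pAB <- predictShift(m, g, both, computeVariance = FALSE)$mean
  expect_equal(pAB, pA + pB, tolerance = 1e-10)
})

test_that("sequential prediction decomposes into independently computed parts", {
  spec <- defaultOracleSpec()
  d <- generateBenchmarkData(40, spec, seed = 51)
  cfg <- quickCfg()
  vac <- trainVacuumModel(d$geoms, d$epsVac, cfg)
  shf <- trainShiftModel(d$geoms, d$envs, d$epsShift, cfg)
  dNew <- generateBenchmarkData(6, spec, seed = 52)
  for (i in seq_along(dNew$geoms)) {
    p <- predictSiteEnergy(vac, shf, dNew$geoms[[i]], dNew$envs[[i]],
                           pigmentId = paste0("p", i))
    pv <- predictGP(vac, cmBundles(dNew$geoms[i]))
    ps <- predictShift(shf, dNew$geoms[[i]], dNew$envs[[i]])
    expect_equal(p@value, pv$mean[1] + ps$mean, tolerance = 1e-10)
    expect_equal(unname(p@components["vac"]), pv$mean[1])
    expect_equal(unname(p@components["shift"]), ps$mean)
    expect_identical(unname(p@components["pol"]), 0)
    expect_equal(p@variance, pv$variance[1] + ps$variance, tolerance = 1e-12)
  }
  # empty environment: value reduces to the vacuum component
  pEmpty <- predictSiteEnergy(vac, shf, dNew$geoms[[1]], emptyEnvironment())
  expect_identical(unname(pEmpty@components["shift"]), 0)
  expect_equal(pEmpty@value, unname(pEmpty@components["vac"]))

  # zero polarizabilities: identical to the electrostatic-embedding result
  envPol <- dNew$envs[[1]]
  envZeroAlpha <- EnvironmentModel(envPol@positions, charges(envPol),
                                   residueIds(envPol),
                                   polarizabilities = rep(0, nSites(envPol)))
  qtr <- TransitionChargeSet(rnorm(nAtoms(dNew$geoms[[1]]), 0, 0.05),
                             neutralize = TRUE)
  pEE <- predictSiteEnergy(vac, shf, dNew$geoms[[1]], dNew$envs[[1]])
  pPol0 <- predictSiteEnergy(vac, shf, dNew$geoms[[1]], envZeroAlpha,
                             polContext = list(charges = qtr))
  expect_equal(pPol0@value, pEE@value, tolerance = 1e-12)
})

test_that("CDC shift matches single-term and brute-force sums and is bilinear", {
  one <- ChromophoreGeometry("X1", "C", rbind(c(0, 0, 0)), "ONE_C")
  env <- EnvironmentModel(rbind(c(5, 0, 0)), -1, 1L)
  expect_equal(cdcShift(0.1, one, env), -0.2879929, tolerance = 1e-7)
  expect_equal(cdcShift(0.1, one, emptyEnvironment()), 0)

  g <- randomGeometry(20, seed = 61)
  envR <- randomEnvironment(4, 4, seed = 62)
  set.seed(63)
  dq <- rnorm(20, 0, 0.05)
  expect_equal(cdcShift(dq, g, envR),
               kE * sum(dq * bfPotential(g, envR)), tolerance = 1e-12)
  # linear in dq and in q
  expect_equal(cdcShift(3 * dq, g, envR), 3 * cdcShift(dq, g, envR),
               tolerance = 1e-12)
  env2 <- EnvironmentModel(envR@positions, 2 * charges(envR),
                           residueIds(envR))
  expect_equal(cdcShift(dq, g, env2), 2 * cdcShift(dq, g, envR),
               tolerance = 1e-12)
})

test_that("vacuum model degrades smoothly on out-of-sample distortions", {
  spec <- defaultOracleSpec(noiseSd = 0)
  d <- generateBenchmarkData(150, spec, seed = 71)
  m <- trainVacuumModel(d$geoms, d$epsVac, quickCfg())
  interp <- generateBenchmarkData(60, spec, seed = 72)
  extrap <- generateBenchmarkData(60, spec, seed = 73, distortionSd = 0.075)
  maeI <- maeScore(predictGP(m, cmBundles(interp$geoms),
                             computeVariance = FALSE)$mean, interp$epsVac)
  maeE <- maeScore(predictGP(m, cmBundles(extrap$geoms),
                             computeVariance = FALSE)$mean, extrap$epsVac)
  expect_lte(maeE, 3 * maeI)
})
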