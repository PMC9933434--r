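test_that("ridge transition-charge model shrinks to mean charges and recovers linear maps", {
  set.seed(101)
  n <- 60; p <- 8; nat <- 5
  CM <- matrix(rnorm(n * p), n)

  # constant targets, huge lambda: predictions ~ the mean charges
  qConst <- matrix(rep(c(0.1, -0.2, 0.05, 0.03, 0.02), each = n), n)
  mBig <- fitTrespModel(CM, qConst, lambda = 1e8, neutralize = FALSE)
  pr <- predictTrespCharges(mBig, rnorm(p))
  expect_equal(transitionCharges(pr), colMeans(qConst), tolerance = 1e-6)

  # exactly linear targets, lambda = 0: exact recovery
  W <- matrix(rnorm(p * nat), p)
  b <- rnorm(nat)
  Q <- sweep(CM %*% W, 2, b, "+")
  m0 <- fitTrespModel(CM, Q, lambda = 0, neutralize = FALSE)
  xNew <- rnorm(p)
  expect_equal(transitionCharges(predictTrespCharges(m0, xNew)),
               as.numeric(xNew %*% W + b), tolerance = 1e-8)

  # neutralization: predicted set sums to zero
  mN <- fitTrespModel(CM, Q, lambda = 1e-6, neutralize = TRUE)
  expect_lt(abs(sum(transitionCharges(predictTrespCharges(mN, xNew)))),
            1e-12)
})

test_that("gamma scaling multiplies charges and couplings scale as gamma_I gamma_J", {
  q <- TransitionChargeSet(c(0.2, -0.2), gamma = 1)
  expect_identical(transitionCharges(scaleCharges(q, 1)),
                   transitionCharges(q))
  expect_equal(transitionCharges(scaleCharges(q, 2)), c(0.4, -0.4))

  posI <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  posJ <- rbind(c(10, 0, 0), c(11.5, 0, 0))
  v0 <- coulombCoupling(q, posI, q, posJ)
  v <- coulombCoupling(scaleCharges(q, 1.3), posI, scaleCharges(q, 0.7),
                       posJ)
  expect_equal(v, 1.3 * 0.7 * v0, tolerance = 1e-12)
})

test_that("Coulomb coupling matches brute force, is symmetric, and flips sign", {
  expect_equal(coulombCoupling(1, rbind(c(0, 0, 0)), 1, rbind(c(1, 0, 0))),
               14.3996454)
  set.seed(7)
  qI <- rnorm(6, 0, 0.1); qJ <- rnorm(8, 0, 0.1)
  posI <- matrix(runif(18, 0, 3), 6)
  posJ <- matrix(runif(24, 0, 3), 8) + 12
  expect_equal(coulombCoupling(qI, posI, qJ, posJ),
               bfCoupling(qI, posI, qJ, posJ), tolerance = 1e-12)
  expect_equal(coulombCoupling(qI, posI, qJ, posJ),
               coulombCoupling(qJ, posJ, qI, posI), tolerance = 1e-12)
  expect_equal(coulombCoupling(qI, posI, -qJ, posJ),
               -coulombCoupling(qI, posI, qJ, posJ), tolerance = 1e-12)
  # two +-0.1 e two-point dipoles 10 A apart vs 4-term sum
  dI <- rbind(c(0, 0, 0), c(0, 0, 1)); dJ <- rbind(c(10, 0, 0), c(10, 0, 1))
  expect_equal(coulombCoupling(c(0.1, -0.1), dI, c(0.1, -0.1), dJ),
               bfCoupling(c(0.1, -0.1), dI, c(0.1, -0.1), dJ),
               tolerance = 1e-12)
  expect_error(coulombCoupling(1, rbind(c(0, 0, 0)), 1, rbind(c(0.5, 0, 0))),
               "overlap")
})

test_that("couplings decay as 1/R^3 for neutral dipole pairs", {
  q <- c(0.1, -0.1)
  dip <- rbind(c(0, 0, 0.5), c(0, 0, -0.5))
  R <- seq(20, 100, by = 10)
  V <- vapply(R, function(r)
    abs(coulombCoupling(q, dip, q, sweep(dip, 2, c(r, 0, 0), "+"))),
    numeric(1))
  slope <- coef(lm(log(V) ~ log(R)))[2]
  expect_equal(unname(slope), -3, tolerance = 0.05)
})

test_that("induced dipoles solve the mutual-polarization system", {
  # single site: mu = alpha E, closed form
  env1 <- EnvironmentModel(rbind(c(0, 0, 0)), 0, 1L, polarizabilities = 1)
  mu <- solveInducedDipoles(env1, 1, rbind(c(10, 0, 0)))
  expect_equal(mu[1, ], c(-0.01, 0, 0), tolerance = 1e-12)

  # alpha = 0 everywhere: zero dipoles
  env0 <- EnvironmentModel(rbind(c(5, 0, 0), c(0, 5, 0)), c(0.1, -0.1),
                           c(1L, 2L), polarizabilities = c(0, 0))
  expect_equal(solveInducedDipoles(env0, c(1, -1),
                                   rbind(c(0, 0, 0), c(1.5, 0, 0))),
               matrix(0, 2, 3), ignore_attr = TRUE)

  # two mutually polarizing sites vs the explicit 6x6 dense solve
  env2 <- EnvironmentModel(rbind(c(6, 0, 0), c(6, 2.5, 0)), c(0, 0),
                           c(1L, 2L), polarizabilities = c(1.2, 0.8))
  src <- rbind(c(0, 0, 0), c(0, 1, 0.5))
  q <- c(0.3, -0.3)
  got <- solveInducedDipoles(env2, q, src)
  expect_equal(got, bfInducedDipoles(env2, q, src),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(attr(got, "residual"), 1e-10)

  # polarization catastrophe guard
  envClose <- EnvironmentModel(rbind(c(6, 0, 0), c(6, 0.5, 0)), c(0, 0),
                               c(1L, 1L), polarizabilities = c(1, 1))
  expect_error(solveInducedDipoles(envClose, 1, rbind(c(0, 0, 0))),
               "catastrophe")
  expect_error(solveInducedDipoles(emptyEnvironment(), 1,
                                   rbind(c(0, 0, 0))),
               "polarizabilities")
})

test_that("polarization site contribution is the -1/2 self-energy and <= 0", {
  one <- ChromophoreGeometry("X1", "C", rbind(c(0, 0, 0)), "ONE_C")
  # zero transition charges
  envP <- EnvironmentModel(rbind(c(4, 0, 0)), 0, 1L, polarizabilities = 2)
  expect_identical(polarizationSiteContribution(0, one, envP), 0)
  # single QM charge + single site: -(1/2) k_e alpha q^2 / r^4
  got <- polarizationSiteContribution(1, one, envP)
  expect_equal(got, -0.5 * kE * 2 / 4^4, tolerance = 1e-12)

  # 5 QM charges, 3 polarizable sites vs the independent implementation
  g5 <- randomGeometry(5, seed = 201)
  env3 <- randomEnvironment(3, 1, seed = 202, alpha = c(0.8, 1.1, 0.5))
  set.seed(203)
  q5 <- rnorm(5, 0, 0.1)
  expect_equal(polarizationSiteContribution(q5, g5, env3),
               bfPolarizationEnergy(q5, coordinates(g5), env3),
               tolerance = 1e-10)
  expect_lte(polarizationSiteContribution(q5, g5, env3), 0)

  # |eps_pol| non-decreasing as any alpha grows
  base <- abs(polarizationSiteContribution(q5, g5, env3))
  for (i in 1:3) {
    a <- polarizabilities(env3)
    a[i] <- a[i] * 1.5
    envUp <- EnvironmentModel(env3@positions, charges(env3),
                              residueIds(env3), polarizabilities = a)
    expect_gte(abs(polarizationSiteContribution(q5, g5, envUp)), base)
  }
})

test_that("screening term matches brute force, is I<->J symmetric, and screens", {
  posI <- rbind(c(0, 0, 1), c(0, 0, -1))
  posJ <- rbind(c(12, 0, 1), c(12, 0, -1))
  qI <- c(0.15, -0.15); qJ <- c(0.12, -0.12)
  envNoAlpha <- EnvironmentModel(rbind(c(6, 0, 0)), 0, 1L)
  expect_identical(screeningTerm(qI, posI, qJ, posJ, envNoAlpha), 0)

  env <- randomEnvironment(3, 1, seed = 301, rMin = 4, rMax = 8,
                           alpha = c(1, 0.6, 1.4))
  got <- screeningTerm(qI, posI, qJ, posJ, env)
  expect_equal(got, bfScreening(qI, posI, qJ, posJ, env), tolerance = 1e-10)
  expect_equal(got, screeningTerm(qJ, posJ, qI, posI, env),
               tolerance = 1e-10)

  # a polarizable site midway between two side-by-side aligned dipoles
  # reduces the Coulomb coupling magnitude
  mid <- EnvironmentModel(rbind(c(6, 0, 0)), 0, 1L, polarizabilities = 1.5)
  V <- coulombCoupling(qI, posI, qJ, posJ)
  S <- screeningTerm(qI, posI, qJ, posJ, mid)
  expect_lt(abs(V + S), abs(V))
})

test_that("energy terms scale linearly with the Coulomb constant probe", {
  # doubling all charges of one chromophore doubles coupling and screening,
  # and quadruples the polarization self-energy (quadratic form)
  g <- randomGeometry(4, seed = 401)
  env <- randomEnvironment(2, 1, seed = 402, alpha = 1)
  set.seed(403)
  q <- rnorm(4, 0, 0.1)
  expect_equal(polarizationSiteContribution(2 * q, g, env),
               4 * polarizationSiteContribution(q, g, env),
               tolerance = 1e-10)
  posJ <- coordinates(g) + 15
  expect_equal(coulombCoupling(2 * q, coordinates(g), q, posJ),
               2 * coulombCoupling(q, coordinates(g), q, posJ),
               tolerance = 1e-12)
})
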