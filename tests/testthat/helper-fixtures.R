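# Shared fixtures and independent brute-force oracles.  The oracles here are
# deliberately naive (double loops, dense solves) and never share code with
# the implementation paths they check.

kE <- excitonML::KE_EV_ANGSTROM

# A small well-separated random geometry (atoms on a jittered grid).
randomGeometry <- function(n, seed = 1, pigmentType = paste0("RND", n, "_", seed),
                           elements = NULL) {
  set.seed(seed)
  grid <- as.matrix(expand.grid(0:3, 0:3, 0:3)) * 2.2
  idx <- sample(nrow(grid), n)
  coords <- grid[idx, , drop = FALSE] + matrix(runif(n * 3, -0.3, 0.3), n, 3)
  if (is.null(elements)) elements <- sample(c("C", "N", "O"), n, replace = TRUE)
  ChromophoreGeometry(paste0("A", seq_len(n)), elements, coords, pigmentType)
}

# A small random environment with nr residues of na atoms each, centered
# at radius ~[rMin, rMax] from the origin.
randomEnvironment <- function(nr = 3, na = 3, seed = 1, rMin = 6, rMax = 15,
                              alpha = NULL) {
  set.seed(seed)
  pos <- NULL; q <- NULL; rid <- NULL
  for (k in seq_len(nr)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    center <- runif(1, rMin, rMax) * u
    local <- matrix(rnorm(na * 3, 0, 0.1), na, 3) +
      1.3 * as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))[seq_len(na), ]
    pos <- rbind(pos, sweep(local, 2, center, "+"))
    q <- c(q, runif(na, -0.4, 0.4))
    rid <- c(rid, rep(k, na))
  }
  al <- if (!is.null(alpha)) rep(alpha, length.out = length(q))
  EnvironmentModel(pos, q, as.integer(rid), polarizabilities = al)
}

# Brute-force electrostatic potential at each QM atom (no cutoff logic).
bfPotential <- function(geom, env) {
  xyz <- coordinates(geom)
  out <- numeric(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    for (m in seq_len(nSites(env))) {
      r <- sqrt(sum((xyz[i, ] - env@positions[m, ])^2))
      out[i] <- out[i] + charges(env)[m] / r
    }
  }
  out
}

# Brute-force TrEsp Coulomb coupling.
bfCoupling <- function(qI, posI, qJ, posJ) {
  v <- 0
  for (i in seq_along(qI)) for (j in seq_along(qJ)) {
    v <- v + qI[i] * qJ[j] / sqrt(sum((posI[i, ] - posJ[j, ])^2))
  }
  kE * v
}

# Independent dense solve of the mutual-polarization system; returns the
# dipole matrix (m x 3) over ALL env atoms (zero where alpha = 0).
bfInducedDipoles <- function(env, q, pos) {
  alpha <- polarizabilities(env)
  act <- which(alpha > 0)
  m <- length(act)
  out <- matrix(0, nSites(env), 3)
  if (m == 0) return(out)
  p <- env@positions[act, , drop = FALSE]
  E <- matrix(0, m, 3)
  for (k in seq_len(m)) for (i in seq_along(q)) {
    dr <- p[k, ] - pos[i, ]
    E[k, ] <- E[k, ] + q[i] * dr / sum(dr^2)^1.5
  }
  A <- matrix(0, 3 * m, 3 * m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    blk <- if (a == b) diag(3) / alpha[act[a]] else {
      dr <- p[a, ] - p[b, ]
      r2 <- sum(dr^2)
      -(3 * outer(dr, dr) / r2 - diag(3)) / r2^1.5
    }
    A[(3 * a - 2):(3 * a), (3 * b - 2):(3 * b)] <- blk
  }
  mu <- solve(A, as.numeric(t(E)))
  out[act, ] <- matrix(mu, ncol = 3, byrow = TRUE)
  out
}

# Independent polarization site energy: -(1/2) k_e sum_m mu_m . E_m.
bfPolarizationEnergy <- function(q, pos, env) {
  mu <- bfInducedDipoles(env, q, pos)
  tot <- 0
  for (m in seq_len(nSites(env))) {
    E <- c(0, 0, 0)
    for (i in seq_along(q)) {
      dr <- env@positions[m, ] - pos[i, ]
      E <- E + q[i] * dr / sum(dr^2)^1.5
    }
    tot <- tot + sum(mu[m, ] * E)
  }
  -0.5 * kE * tot
}

# Independent screening term: -k_e sum_m mu_m({q}_J) . E_m({q}_I).
bfScreening <- function(qI, posI, qJ, posJ, env) {
  mu <- bfInducedDipoles(env, qJ, posJ)
  tot <- 0
  for (m in seq_len(nSites(env))) {
    E <- c(0, 0, 0)
    for (i in seq_along(qI)) {
      dr <- env@positions[m, ] - posI[i, ]
      E <- E + qI[i] * dr / sum(dr^2)^1.5
    }
    tot <- tot + sum(mu[m, ] * E)
  }
  -kE * tot
}

# Dense-matrix GP posterior oracle (solve(), no Cholesky), including the
# implementation's diagonal jitter so the two routes target the same system.
bfGPPosterior <- function(K, y, noise, mu, Kstar, kss) {
  Kr <- K + diag(noise + 1e-10, nrow(K))
  Kinv <- solve(Kr)
  alpha <- Kinv %*% (y - mu)
  mean <- mu + as.numeric(Kstar %*% alpha)
  var <- kss - diag(Kstar %*% Kinv %*% t(Kstar))
  list(mean = mean, variance = pmax(var, 0))
}

# Dense LML oracle via determinant and solve.
bfLML <- function(K, y, noise, mu) {
  Kr <- K + diag(noise + 1e-10, nrow(K))
  r <- y - mu
  as.numeric(-0.5 * t(r) %*% solve(Kr, r) -
             0.5 * determinant(Kr)$modulus -
             length(y) / 2 * log(2 * pi))
}

# Independent exhaustive greedy farthest-point-sampling oracle.
bfFPS <- function(X, k, start) {
  X <- as.matrix(X)
  sel <- start
  while (length(sel) < k) {
    best <- NA; bestD <- -Inf
    for (cand in seq_len(nrow(X))) {
      if (cand %in% sel) next
      dmin <- min(vapply(sel, function(s)
        sqrt(sum((X[cand, ] - X[s, ])^2)), numeric(1)))
      if (dmin > bestD) { bestD <- dmin; best <- cand }  # first index wins ties
    }
    sel <- c(sel, best)
  }
  sel
}

# Build (cm, pot) bundles from a benchmark data list.
dataBundles <- function(d, cutoffA = 30) {
  mapply(function(g, e) list(cm = as.numeric(coulombMatrix(g)),
                             pot = mmPotential(g, e, cutoffA)),
         d$geoms, d$envs, SIMPLIFY = FALSE)
}

cmBundles <- function(geoms) {
  lapply(geoms, function(g) list(cm = as.numeric(coulombMatrix(g))))
}

shiftPredictions <- function(model, d) {
  vapply(seq_along(d$geoms), function(i) {
    predictShift(model, d$geoms[[i]], d$envs[[i]],
                 computeVariance = FALSE)$mean
  }, numeric(1))
}
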