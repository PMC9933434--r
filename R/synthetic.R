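# Synthetic fixtures: distorted macrocycle-like geometries, clustered charge
# environments, and analytic oracle targets with the same structure the
# models assume (smooth nonlinear vacuum energies on the Coulomb matrix;
# geometry-dependent linear response of the shift to the MM potential).
# Everything is deterministic given a seed; no global RNG state leaks out.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Undistorted macrocycle-like scaffold: nHeavy atoms on a planar ring with
# 1.39 A bonds (every 4th a nitrogen, porphyrin-like), plus nH hydrogens
# pointing outward.
toyScaffold <- function(nHeavy = 17, nH = 4, pigmentType = "TOY") {
  stopifnot(nHeavy >= 5)
  radius <- 1.39 / (2 * sin(pi / nHeavy))
  ang <- 2 * pi * (seq_len(nHeavy) - 1) / nHeavy
  coords <- cbind(radius * cos(ang), radius * sin(ang), 0)
  elements <- rep("C", nHeavy)
  elements[seq(1, nHeavy, by = 4)] <- "N"
  names <- paste0(elements, seq_len(nHeavy))
  if (nH > 0) {
    hIdx <- round(seq(2, nHeavy, length.out = nH))
    hCoords <- coords[hIdx, , drop = FALSE] *
      (radius + 1.09) / radius
    coords <- rbind(coords, hCoords)
    elements <- c(elements, rep("H", nH))
    names <- c(names, paste0("H", seq_len(nH)))
  }
  ChromophoreGeometry(names, elements, coords, pigmentType)
}

#' Generate an ensemble of distorted macrocycle-like geometries
#'
#' A planar ring-like heavy-atom scaffold (every fourth atom a nitrogen,
#' outward hydrogens) receives per-sample Gaussian bond-length and
#' out-of-plane jitter plus an "improper-like" mode that pushes the first
#' nitrogen out of the ring plane, emulating the large-amplitude macrocycle
#' doming seen in molecular-dynamics ensembles of chlorophyll.
#'
#' @param n number of geometries.
#' @param nHeavy heavy-atom count (default 17).
#' @param distortionSd Gaussian jitter standard deviation, Angstrom
#'   (default 0.05).
#' @param seed integer seed; the ensemble is reproducible.
#' @param pigmentType tag registered (first use) as the canonical order.
#' @param nH number of hydrogens on the scaffold.
#' @return List of [ChromophoreGeometry-class]; all pair distances > 0.9 A.
#' @export
generateChromophoreEnsemble <- function(n, nHeavy = 17, distortionSd = 0.05,
                                        seed = 1, pigmentType = "TOY",
                                        nH = 4) {
  base <- toyScaffold(nHeavy, nH, pigmentType)
  registerPigmentType(pigmentType, atomNames(base))
  nat <- nAtoms(base)
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        jitter <- matrix(stats::rnorm(nat * 3, 0, distortionSd), nat, 3)
        # improper-like mode: first atom (a nitrogen) moves through the plane
        dome <- stats::runif(1, -1, 1) * 6 * distortionSd
        coords <- coordinates(base) + jitter
        coords[1, 3] <- coords[1, 3] + dome
        d <- crossDist(coords, coords)
        if (min(d[upper.tri(d)]) > 0.9) break
      }
      ChromophoreGeometry(atomNames(base), base@elements, coords,
                          pigmentType)
    })
  })
}

#' Generate a clustered point-charge environment
#'
#' Residues are spatial clusters of \code{atomsPerResidue} sites placed on a
#' jittered cube-corner template around centers drawn in a spherical shell
#' (inner radius 8 A, outer \code{boxA}) around the origin, where the
#' chromophore sits.  A per-residue net charge is drawn with standard
#' deviation \code{chargeSd} and distributed over the residue's atoms.
#' Optional isotropic polarizabilities are uniform in \code{alphaRange}.
#'
#' @param nResidues number of residues.
#' @param atomsPerResidue sites per residue (<= 8).
#' @param boxA outer placement radius, Angstrom (default 25).
#' @param chargeSd per-residue net-charge standard deviation, e
#'   (default 0.25, a typical partial-charge imbalance of a polar residue).
#' @param alphaRange NULL, or length-2 range of polarizabilities, A^3.
#' @param seed integer seed.
#' @return An [EnvironmentModel-class]; site-site distances exceed 1 A so
#'   the environment is safe for the induced-dipole solver.
#' @export
generateEnvironment <- function(nResidues, atomsPerResidue = 4, boxA = 25,
                                chargeSd = 0.25, alphaRange = NULL,
                                seed = 1) {
  stopifnot(atomsPerResidue >= 1, atomsPerResidue <= 8, boxA > 10)
  template <- as.matrix(expand.grid(c(-0.9, 0.9), c(-0.9, 0.9),
                                    c(-0.9, 0.9)))
  withSeed(seed, {
    centers <- matrix(NA_real_, nResidues, 3)
    placed <- 0
    while (placed < nResidues) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u * u))
      r <- stats::runif(1, 8, boxA)
      cand <- r * u
      if (placed == 0 ||
          min(crossDist(rbind(cand), centers[seq_len(placed), ,
                                             drop = FALSE])) > 5) {
        placed <- placed + 1
        centers[placed, ] <- cand
      }
    }
    pos <- NULL; q <- NULL; rid <- NULL
    for (k in seq_len(nResidues)) {
      local <- template[seq_len(atomsPerResidue), , drop = FALSE] +
        matrix(stats::rnorm(atomsPerResidue * 3, 0, 0.1), atomsPerResidue, 3)
      pos <- rbind(pos, sweep(local, 2, centers[k, ], "+"))
      net <- stats::rnorm(1, 0, chargeSd)
      qk <- stats::rnorm(atomsPerResidue, 0, 0.1)
      qk <- qk - mean(qk) + net / atomsPerResidue
      q <- c(q, qk)
      rid <- c(rid, rep(k, atomsPerResidue))
    }
    alpha <- NULL
    if (!is.null(alphaRange)) {
      alpha <- stats::runif(length(q), alphaRange[1], alphaRange[2])
    }
    EnvironmentModel(pos, q, as.integer(rid),
                     residueNames = paste0("RES", rid),
                     polarizabilities = alpha)
  })
}

#' Default oracle specification for synthetic targets
#'
#' The vacuum oracle is a smooth nonlinear function of the Coulomb matrix in
#' the 2.0-2.2 eV range; the shift oracle is a geometry-dependent linear
#' response to the MM potential that vanishes exactly for an empty
#' environment.  The default numbers place the vacuum energies around
#' 2.105 eV with a spread of a few tens of meV, matching the scale of
#' thermal site-energy fluctuations of chlorophyll.
#'
#' @param nHeavy heavy-atom count of the geometries the oracle will see.
#' @param nAtomsTotal total atom count (heavy + H).
#' @param seed integer seed for the oracle's fixed random directions.
#' @param baseEnergy center of the vacuum energies, eV.
#' @param weightScale scale of the linear Coulomb-matrix response, eV.
#' @param nonlinearityScale amplitude of the saturating quadratic term, eV.
#' @param responseChargeSd scale of the geometry-independent effective
#'   response charges, e.
#' @param geometryCoupling scale of the geometry dependence of the response
#'   charges, e per Coulomb-matrix unit; 0 gives a purely linear shift
#'   oracle that a linear-kernel GP can represent exactly.
#' @param noiseSd Gaussian target noise, eV.
#' @return Named list (class \code{oracleSpec}) with the reference Coulomb
#'   matrix of the undistorted scaffold and all response coefficients.
#' @export
defaultOracleSpec <- function(nHeavy = 17, nAtomsTotal = nHeavy + 4,
                              seed = 42, baseEnergy = 2.105,
                              weightScale = 0.04,
                              nonlinearityScale = 0.02,
                              responseChargeSd = 0.01,
                              geometryCoupling = 0.002,
                              noiseSd = 5e-4) {
  base <- toyScaffold(nHeavy, nAtomsTotal - nHeavy, "ORACLE_REF")
  cmRef <- as.numeric(coulombMatrix(base))
  ncm <- length(cmRef)
  withSeed(seed, {
    w <- stats::rnorm(ncm)
    w <- w / sqrt(sum(w * w)) * weightScale
    v <- stats::rnorm(ncm)
    v <- v / sqrt(sum(v * v))
    rc <- stats::rnorm(nAtomsTotal, 0, responseChargeSd)
    gc <- matrix(stats::rnorm(nAtomsTotal * ncm), nAtomsTotal, ncm)
    gc <- gc / sqrt(rowSums(gc^2)) * geometryCoupling
    structure(list(
      baseEnergy = baseEnergy, cmRef = cmRef, weights = w,
      nonlinearityScale = nonlinearityScale, nonlinearityDirection = v,
      responseCharges = rc, geometryCoupling = gc,
      noiseSd = noiseSd, seed = seed), class = "oracleSpec")
  })
}

#' Analytic oracle for the vacuum excitation energy
#'
#' base + <w, cm - cmRef> + s * tanh(<v, cm - cmRef>^2) + noise.  The noise
#' draw is deterministic given the spec seed and the sample index.
#'
#' @param geom a [ChromophoreGeometry-class].
#' @param spec an \code{oracleSpec} from [defaultOracleSpec()].
#' @param sampleIndex integer index used to seed the per-sample noise.
#' @return Vacuum excitation energy, eV.
#' @export
oracleVacuumEnergy <- function(geom, spec, sampleIndex = 1) {
  cm <- as.numeric(coulombMatrix(geom))
  stopifnot(length(cm) == length(spec$cmRef))
  dcm <- cm - spec$cmRef
  e <- spec$baseEnergy + sum(spec$weights * dcm) +
    spec$nonlinearityScale * tanh(sum(spec$nonlinearityDirection * dcm)^2)
  if (spec$noiseSd > 0) {
    e <- e + withSeed(spec$seed * 1000 + sampleIndex,
                      stats::rnorm(1, 0, spec$noiseSd))
  }
  e
}

#' Analytic oracle for the electrochromic shift
#'
#' k_e <phi(geom, env), c(geom)> with geometry-dependent effective charges
#' c(geom) = responseCharges + geometryCoupling (cm - cmRef).  Exactly zero
#' for an empty environment and linear in the environment charges.
#'
#' @param geom a [ChromophoreGeometry-class].
#' @param env an [EnvironmentModel-class].
#' @param spec an \code{oracleSpec}.
#' @param cutoffA cutoff passed to [mmPotential()].
#' @param sampleIndex integer index for the deterministic noise draw.
#' @return Electrochromic shift, eV.
#' @export
oracleShift <- function(geom, env, spec, cutoffA = 30, sampleIndex = 1) {
  phi <- mmPotential(geom, env, cutoffA)
  if (all(phi == 0)) return(0)
  cm <- as.numeric(coulombMatrix(geom))
  cEff <- spec$responseCharges +
    as.numeric(spec$geometryCoupling %*% (cm - spec$cmRef))
  s <- KE_EV_ANGSTROM * sum(phi * cEff)
  if (spec$noiseSd > 0) {
    s <- s + withSeed(spec$seed * 2000 + sampleIndex,
                      stats::rnorm(1, 0, spec$noiseSd))
  }
  s
}

#' Generate a complete in-memory benchmark set
#'
#' Geometries, per-sample environments, and oracle targets for both the
#' vacuum and shift problems.
#'
#' @param n number of samples.
#' @param spec an \code{oracleSpec}.
#' @param seed integer seed.
#' @param nHeavy,distortionSd,pigmentType passed to
#'   [generateChromophoreEnsemble()].
#' @param nResidues,atomsPerResidue,boxA,chargeSd,alphaRange passed to
#'   [generateEnvironment()] (one independent environment per sample).
#' @param cutoffA potential cutoff for the shift oracle.
#' @return List with \code{geoms}, \code{envs}, \code{epsVac},
#'   \code{epsShift}, and the generating \code{spec}/\code{seed}.
#' @export
generateBenchmarkData <- function(n, spec = defaultOracleSpec(), seed = 1,
                                  nHeavy = 17, distortionSd = 0.05,
                                  pigmentType = "TOY", nResidues = 12,
                                  atomsPerResidue = 4, boxA = 25,
                                  chargeSd = 0.25, alphaRange = NULL,
                                  cutoffA = 30) {
  geoms <- generateChromophoreEnsemble(n, nHeavy, distortionSd, seed,
                                       pigmentType)
  envs <- lapply(seq_len(n), function(i) {
    generateEnvironment(nResidues, atomsPerResidue, boxA, chargeSd,
                        alphaRange, seed = seed * 100000 + i)
  })
  epsVac <- vapply(seq_len(n), function(i) {
    oracleVacuumEnergy(geoms[[i]], spec, sampleIndex = i)
  }, numeric(1))
  epsShift <- vapply(seq_len(n), function(i) {
    oracleShift(geoms[[i]], envs[[i]], spec, cutoffA, sampleIndex = i)
  }, numeric(1))
  list(geoms = geoms, envs = envs, epsVac = epsVac, epsShift = epsShift,
       spec = spec, seed = seed, cutoffA = cutoffA)
}

#' Write a training/test benchmark bundle to disk
#'
#' Writes XYZ geometries, environment CSV tables, a target table and a JSON
#' manifest recording the generating configuration, seed and schema version.
#' Regeneration with the same seed is bit-identical.
#'
#' @param dir output directory (created).
#' @param nTrain,nTest sample counts (defaults 600/200).
#' @param seed integer seed.
#' @param config optional named list overriding generator arguments
#'   (nHeavy, distortionSd, nResidues, atomsPerResidue, boxA, chargeSd,
#'   alphaRange, cutoffA, plus oracle-spec overrides under \code{oracle}).
#' @return Invisibly, the manifest list.
#' @export
makeBenchmarkBundle <- function(dir, nTrain = 600, nTest = 200, seed = 1,
                                config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- function(n, s) {
    do.call(generateBenchmarkData, c(list(
      n = n,
      spec = do.call(defaultOracleSpec, config$oracle %||% list()),
      seed = s),
      config[setdiff(names(config), "oracle")]))
  }
  sets <- list(train = gen(nTrain, seed), test = gen(nTest, seed + 1))
  targetRows <- list()
  for (setName in names(sets)) {
    d <- sets[[setName]]
    for (i in seq_along(d$geoms)) {
      id <- sprintf("%s_%04d", setName, i)
      writeXYZ(d$geoms[[i]], file.path(dir, paste0(id, ".xyz")))
      writeEnvironment(d$envs[[i]], file.path(dir, paste0(id, "_env.csv")))
      targetRows[[length(targetRows) + 1]] <- data.frame(
        sample_id = id, set = setName,
        eps_vac = d$epsVac[i], eps_shift = d$epsShift[i])
    }
  }
  targets <- do.call(rbind, targetRows)
  writeTable <- file.path(dir, "targets.csv")
  utils::write.csv(format(targets, digits = 12, trim = TRUE,
                          scientific = FALSE),
                   writeTable, row.names = FALSE, quote = FALSE)
  manifest <- list(
    schemaVersion = 1L, seed = seed, nTrain = nTrain, nTest = nTest,
    config = config, units = list(length = "Angstrom", charge = "e",
                                  energy = "eV"),
    files = list(targets = "targets.csv",
                 geometryPattern = "{sample_id}.xyz",
                 environmentPattern = "{sample_id}_env.csv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a benchmark bundle written by [makeBenchmarkBundle()]
#'
#' @param dir bundle directory.
#' @param set "train" or "test".
#' @return List with \code{geoms}, \code{envs}, \code{epsVac},
#'   \code{epsShift}, \code{ids} and the \code{manifest}.
#' @export
readBenchmarkBundle <- function(dir, set = c("train", "test")) {
  set <- match.arg(set)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  targets <- utils::read.csv(file.path(dir, "targets.csv"),
                             stringsAsFactors = FALSE)
  targets <- targets[targets$set == set, , drop = FALSE]
  geoms <- lapply(targets$sample_id, function(id) {
    readXYZ(file.path(dir, paste0(id, ".xyz")),
            pigmentType = manifest$config$pigmentType %||% "TOY")
  })
  envs <- lapply(targets$sample_id, function(id) {
    readEnvironment(file.path(dir, paste0(id, "_env.csv")))
  })
  list(geoms = geoms, envs = envs, epsVac = targets$eps_vac,
       epsShift = targets$eps_shift, ids = targets$sample_id,
       manifest = manifest)
}
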