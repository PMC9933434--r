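Package: excitonML
Title: Sequential Machine Learning of Frenkel Exciton Hamiltonians for
    Pigment-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts full Frenkel exciton Hamiltonians (site energies and
    excitonic couplings) of chromophores embedded in a classical point-charge
    environment using a sequential strategy: a Gaussian-process model of the
    vacuum excitation energy on Coulomb-matrix descriptors, an additive
    Gaussian-process model of the electrochromic shift on MM electrostatic
    potentials with a physics-constrained composite kernel, and analytic
    polarization and screening corrections computed from transition charges
    and induced dipoles.  Includes the charge-density-coupling (CDC) baseline,
    per-residue influence analysis, farthest point sampling, cross-validated
    scoring, Gaussian-broadened stick spectra, and a synthetic-fixture
    generator with analytic oracles so every model is trainable and testable
    without external quantum-chemistry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'pigments.R'
    'descriptors.R'
    'kernels.R'
    'gp.R'
    'siteEnergy.R'
    'tresp.R'
    'exciton.R'
    'sampling.R'
    'synthetic.R'
    'io.R'
    'config.R'
    'cli.R'
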