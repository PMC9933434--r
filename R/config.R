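# Run configuration: plain-text YAML file, validated before computation,
# with flag-level overrides layered on top.

#' Default run configuration
#'
#' @param ... named overrides of the defaults.
#' @return Named list: \code{cutoffA} (30 Angstrom, residue-inclusion cutoff
#'   for MM potentials), \code{restarts} (5, hyperparameter optimizer
#'   restarts), \code{seed}, \code{kernelBounds} (named list of length-2
#'   ranges), \code{gamma} (named per-pigment-type transition-charge scaling,
#'   default 1), \code{units} echo.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    cutoffA = 30,
    restarts = 5,
    seed = 1,
    kernelBounds = list(),
    gamma = list(default = 1),
    units = list(length = "Angstrom", charge = "e", energy = "eV"))
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  validateRunConfig(cfg)
}

#' Validate a run configuration
#'
#' @param cfg named list.
#' @return The validated config (invisibly usable); errors on bad values.
#' @export
validateRunConfig <- function(cfg) {
  if (!is.numeric(cfg$cutoffA) || cfg$cutoffA <= 0) {
    stop("config: cutoffA must be a positive number (Angstrom)")
  }
  if (!is.numeric(cfg$restarts) || cfg$restarts < 1) {
    stop("config: restarts must be >= 1")
  }
  if (!is.numeric(cfg$seed)) stop("config: seed must be an integer")
  if (!is.null(cfg$kernelBounds)) {
    ok <- vapply(cfg$kernelBounds, function(b) {
      is.numeric(b) && length(b) == 2 && all(b > 0) && b[2] > b[1]
    }, logical(1))
    if (length(ok) && !all(ok)) {
      stop("config: every kernelBounds entry must be a positive increasing ",
           "length-2 range")
    }
  }
  cfg
}

#' Read a run configuration from a YAML file, with overrides
#'
#' File values are layered over [defaultRunConfig()]; \code{overrides} (e.g.
#' parsed command-line flags) are layered over the file.
#'
#' @param path YAML file path, or NULL for defaults only.
#' @param overrides named list applied last.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    fromFile <- yaml::read_yaml(path)
    cfg[names(fromFile)] <- fromFile
  }
  cfg[names(overrides)] <- overrides
  validateRunConfig(cfg)
}

#' Provenance block for outputs
#'
#' @param cfg a validated run configuration.
#' @return Named list with the package version, a config digest (sum of the
#'   deparse character codes; stable across sessions), the seed, and a
#'   frozen copy of the config.
#' @export
provenanceBlock <- function(cfg) {
  frozen <- deparse(cfg[order(names(cfg))])
  digest <- sum(utf8ToInt(paste(frozen, collapse = ""))) %% 1000000007
  list(package = "excitonML",
       version = as.character(utils::packageVersion("excitonML")),
       configDigest = digest, seed = cfg$seed, config = cfg)
}
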