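# Readers and writers: XYZ and a PDB subset for geometries, CSV environment
# tables, plain-text Hamiltonians with JSON sidecars.

#' Read a chromophore geometry from an XYZ file
#'
#' Standard XYZ (count line, comment line, then \code{element x y z} records,
#' Angstrom).  An optional fifth column carries canonical atom names; when
#' absent, names default to element + position.
#'
#' @param path file path.
#' @param pigmentType tag attached to the geometry.
#' @return A [ChromophoreGeometry-class].
#' @export
readXYZ <- function(path, pigmentType = "UNK") {
  lines <- readLines(path)
  if (length(lines) < 2) stop("malformed XYZ: fewer than 2 lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line is not an atom count")
  if (length(lines) < 2 + n) stop("malformed XYZ: atom-count mismatch")
  recs <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  bad <- vapply(recs, length, integer(1)) < 4
  if (any(bad)) stop("malformed XYZ record at atom ", which(bad)[1])
  elements <- vapply(recs, `[`, character(1), 1)
  coords <- t(vapply(recs, function(r) as.numeric(r[2:4]), numeric(3)))
  if (anyNA(coords)) stop("malformed XYZ: non-numeric coordinate")
  names <- vapply(seq_along(recs), function(i) {
    if (length(recs[[i]]) >= 5) recs[[i]][5]
    else paste0(elements[i], i)
  }, character(1))
  atomicNumber(elements)  # validates element symbols
  ChromophoreGeometry(names, elements, coords, pigmentType)
}

#' Write a chromophore geometry as XYZ
#'
#' Coordinates are written with 6 decimals (round-trip to 1e-6 Angstrom);
#' canonical atom names go in a fifth column so they survive the round-trip.
#'
#' @param geom a [ChromophoreGeometry-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeXYZ <- function(geom, path) {
  xyz <- coordinates(geom)
  lines <- c(
    as.character(nAtoms(geom)),
    paste0("pigment_type=", pigmentType(geom)),
    sprintf("%-2s %14.6f %14.6f %14.6f %s", geom@elements,
            xyz[, 1], xyz[, 2], xyz[, 3], atomNames(geom)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a chromophore geometry from a PDB file (subset)
#'
#' Parses ATOM/HETATM records (fixed columns), maps atom names, and reorders
#' into the canonical order of the pigment type when one is registered.
#' Element symbols are taken from columns 77-78 when present, otherwise
#' inferred from the atom name.
#'
#' @param path file path.
#' @param pigmentType tag; when registered, atoms are reordered to canon.
#' @return A [ChromophoreGeometry-class].
#' @export
readPDBGeometry <- function(path, pigmentType = "UNK") {
  lines <- readLines(path)
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (!length(rec)) stop("malformed PDB: no ATOM/HETATM records")
  name <- trimws(substr(rec, 13, 16))
  x <- as.numeric(substr(rec, 31, 38))
  y <- as.numeric(substr(rec, 39, 46))
  z <- as.numeric(substr(rec, 47, 54))
  if (anyNA(c(x, y, z))) stop("malformed PDB: non-numeric coordinate")
  elem <- trimws(substr(rec, 77, 78))
  infer <- elem == "" | is.na(elem)
  elem[infer] <- sub("[0-9'].*$", "", name[infer])
  elem <- paste0(toupper(substr(elem, 1, 1)),
                 tolower(substr(elem, 2, 2)))
  elem <- trimws(elem)
  geom <- ChromophoreGeometry(name, elem, cbind(x, y, z), pigmentType)
  canonicalizeGeometry(geom)
}

#' Read an environment table
#'
#' Whitespace- or comma-separated columns: residue_id, residue_name,
#' atom_name, x, y, z, q, and optionally alpha.
#'
#' @param path file path.
#' @return An [EnvironmentModel-class].
#' @export
readEnvironment <- function(path) {
  first <- readLines(path, n = 1)
  df <- if (grepl(",", first)) {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  }
  need <- c("residue_id", "residue_name", "atom_name", "x", "y", "z", "q")
  if (!all(need %in% names(df))) {
    stop("environment table must have columns: ",
         paste(need, collapse = ", "))
  }
  EnvironmentModel(cbind(df$x, df$y, df$z), df$q,
                   as.integer(df$residue_id), df$residue_name,
                   polarizabilities = df[["alpha"]])
}

#' Write an environment table (CSV)
#'
#' @param env an [EnvironmentModel-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEnvironment <- function(env, path) {
  m <- nSites(env)
  df <- data.frame(
    residue_id = env@residueIds,
    residue_name = env@residueNames,
    atom_name = paste0("M", seq_len(m)),
    x = sprintf("%.10g", env@positions[, 1]),
    y = sprintf("%.10g", env@positions[, 2]),
    z = sprintf("%.10g", env@positions[, 3]),
    q = sprintf("%.10g", env@charges))
  if (isPolarizable(env)) df$alpha <- sprintf("%.10g", env@polarizabilities)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an exciton Hamiltonian: plain-text matrix + JSON sidecar
#'
#' @param H an [ExcitonHamiltonian-class].
#' @param path output path for the matrix (whitespace-separated, eV); the
#'   sidecar goes to \code{paste0(path, ".json")} with labels and provenance.
#' @return Invisibly, \code{path}.
#' @export
writeHamiltonian <- function(H, path) {
  m <- H@matrix
  writeLines(c("# exciton Hamiltonian, eV",
               apply(m, 1, function(r) paste(sprintf("%.10e", r),
                                             collapse = " "))),
             path)
  jsonlite::write_json(list(siteLabels = H@siteLabels,
                            units = "eV", provenance = H@provenance),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read an exciton Hamiltonian written by [writeHamiltonian()]
#'
#' @param path matrix file path (expects the JSON sidecar next to it).
#' @return An [ExcitonHamiltonian-class].
#' @export
readHamiltonian <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  side <- paste0(path, ".json")
  labels <- as.character(seq_len(nrow(m)))
  prov <- list()
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    labels <- meta$siteLabels
    prov <- as.list(meta$provenance %||% list())
  }
  m <- (m + t(m)) / 2   # symmetrize away print round-off
  new("ExcitonHamiltonian", matrix = m, siteLabels = labels,
      provenance = prov)
}

#' Read a transition-charge table
#'
#' CSV with columns atom_name and q_tr (e).
#'
#' @param path file path.
#' @param gamma scaling factor stored on the set.
#' @return A [TransitionChargeSet-class] in file order.
#' @export
readTransitionCharges <- function(path, gamma = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("atom_name", "q_tr") %in% names(df))) {
    stop("transition-charge table must have columns atom_name, q_tr")
  }
  TransitionChargeSet(df$q_tr, gamma = gamma)
}
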