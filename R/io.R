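## Readers and writers: extended XYZ with a Lattice header for crystals, a
## JSON topology sidecar per compound, CSV ledgers/pair tables, JSON
## provenance records. Full double precision throughout; display rounding is
## the caller's concern.

fmtNum <- function(x) vapply(x, function(v) format(v, digits = 17L), character(1L))

## write.csv keeping the full double precision of numeric columns
writeCsvFull <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- fmtNum(out[[j]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a crystal to extended XYZ (+ JSON topology sidecar)
#'
#' @param xtal a \linkS4class{CrystalStructure}.
#' @param path output .xyz path; the topology sidecar is written next to it
#'   with extension .json unless \code{topologyPath} is given.
#' @param topologyPath optional sidecar path.
#' @return \code{path}, invisibly.
#' @export
writeCrystal <- function(xtal, path, topologyPath = xyzSidecar(path)) {
  mol <- xtal@molecule
  n <- nAtoms(mol)
  Z <- zMolecules(xtal)
  X <- do.call(rbind, xtal@coordsList)
  lat <- paste(fmtNum(as.numeric(t(latticeVectors(xtal)))), collapse = " ")
  header <- sprintf(
    'Lattice="%s" Properties=species:S:1:pos:R:3:mol:I:1 structure_id=%s compound_id=%s z=%d',
    lat, structureId(xtal), compoundId(xtal), Z)
  lines <- c(as.character(n * Z), header,
             vapply(seq_len(n * Z), function(i)
               paste(rep(mol@elements, Z)[i],
                     fmtNum(X[i, 1L]), fmtNum(X[i, 2L]), fmtNum(X[i, 3L]),
                     (i - 1L) %/% n + 1L), character(1L)))
  writeLines(lines, path)
  writeTopology(mol, topologyPath)
  invisible(path)
}

xyzSidecar <- function(path) sub("\\.xyz$", ".json", path)

#' Write a molecule topology/parameter sidecar (JSON)
#'
#' @param mol a \linkS4class{Molecule}.
#' @param path output .json path.
#' @return \code{path}, invisibly.
#' @export
writeTopology <- function(mol, path) {
  obj <- list(
    compound_id = mol@compoundId,
    elements = mol@elements,
    charges = mol@charges,
    bonds = mol@bonds,
    angles = mol@angles,
    torsions = mol@torsions,
    rotatable = mol@rotatable,
    bond_pars = mol@bondPars,
    angle_pars = mol@anglePars,
    torsion_pars = lapply(mol@torsionPars, function(p)
      list(V = p$V, n = p$n, gamma = p$gamma)),
    sigma = mol@sigma,
    epsilon = mol@epsilon,
    coords = mol@coords)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a molecule topology sidecar
#'
#' @param path .json path written by \code{\link{writeTopology}}.
#' @return a \linkS4class{Molecule}.
#' @export
readTopology <- function(path) {
  if (!file.exists(path))
    stop(sprintf("missing topology sidecar '%s'", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asMat <- function(x, ncol, mode = "double") {
    if (is.null(x) || !length(x)) {
      m <- matrix(vector(mode, 0L), ncol = ncol)
    } else {
      m <- if (is.matrix(x)) x else matrix(unlist(x), ncol = ncol, byrow = TRUE)
    }
    storage.mode(m) <- mode
    m
  }
  nT <- nrow(asMat(obj$torsions, 4L, "integer"))
  tpars <- obj$torsion_pars
  tp <- lapply(seq_len(nT), function(i) {
    p <- if (is.data.frame(tpars))
      list(V = tpars$V[[i]], n = tpars$n[[i]], gamma = tpars$gamma[[i]])
    else tpars[[i]]
    data.frame(V = as.numeric(unlist(p$V)), n = as.numeric(unlist(p$n)),
               gamma = as.numeric(unlist(p$gamma)))
  })
  Molecule(elements = as.character(obj$elements),
           coords = asMat(obj$coords, 3L),
           bonds = asMat(obj$bonds, 2L, "integer"),
           bondPars = asMat(obj$bond_pars, 2L),
           anglePars = asMat(obj$angle_pars, 2L), torsionPars = tp,
           charges = as.numeric(obj$charges), sigma = as.numeric(obj$sigma),
           epsilon = as.numeric(obj$epsilon),
           angles = asMat(obj$angles, 3L, "integer"),
           torsions = asMat(obj$torsions, 4L, "integer"),
           rotatable = as.integer(unlist(obj$rotatable)),
           compoundId = as.character(obj$compound_id))
}

#' Read a crystal from extended XYZ (+ topology sidecar)
#'
#' Expects the two-line extended-XYZ header (atom count, then a comment line
#' with a \code{Lattice="..."} entry) and a per-atom molecule-index column.
#' Round-trip with \code{\link{writeCrystal}} is stable to full double
#' precision.
#'
#' @param path .xyz path.
#' @param topologyPath sidecar path (default: same name with .json).
#' @return a \linkS4class{CrystalStructure}.
#' @export
readCrystal <- function(path, topologyPath = xyzSidecar(path)) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop(sprintf("'%s': truncated file (line 1)", path))
  natTot <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(natTot))
    stop(sprintf("'%s' line 1: expected an atom count, got '%s'", path, lines[1L]))
  m <- regmatches(lines[2L], regexec('Lattice="([^"]+)"', lines[2L]))[[1L]]
  if (length(m) < 2L)
    stop(sprintf("'%s' line 2: missing Lattice=\"...\" entry", path))
  latv <- as.numeric(strsplit(trimws(m[2L]), "\\s+")[[1L]])
  if (length(latv) != 9L || any(is.na(latv)))
    stop(sprintf("'%s' line 2: Lattice must hold 9 numbers", path))
  lattice <- matrix(latv, 3L, 3L, byrow = TRUE)
  sid <- regmatches(lines[2L], regexec("structure_id=(\\S+)", lines[2L]))[[1L]]
  sid <- if (length(sid) >= 2L) sid[2L] else "XTAL"
  if (length(lines) < 2L + natTot)
    stop(sprintf("'%s': expected %d atom lines, found %d (after line 2)",
                 path, natTot, length(lines) - 2L))
  mol <- readTopology(topologyPath)
  n <- nAtoms(mol)
  if (natTot %% n != 0L)
    stop(sprintf("'%s': atom count %d is not a multiple of the %d-atom topology",
                 path, natTot, n))
  Z <- natTot %/% n
  X <- matrix(0, natTot, 3L)
  for (i in seq_len(natTot)) {
    f <- strsplit(trimws(lines[2L + i]), "\\s+")[[1L]]
    if (length(f) < 4L)
      stop(sprintf("'%s' line %d: malformed atom line", path, 2L + i))
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(xyz)))
      stop(sprintf("'%s' line %d: non-numeric coordinates", path, 2L + i))
    X[i, ] <- xyz
  }
  coordsList <- lapply(seq_len(Z), function(mi)
    X[((mi - 1L) * n + 1L):(mi * n), , drop = FALSE])
  CrystalStructure(lattice, mol, coordsList, structureId = sid,
                   compoundId = compoundId(mol))
}

#' Write conformers to multi-frame extended XYZ plus a CSV ranking table
#'
#' @param cs a \linkS4class{ConformerSet}.
#' @param mol the \linkS4class{Molecule} the conformers belong to.
#' @param xyzPath multi-frame .xyz output path.
#' @param csvPath ranking table output path.
#' @return \code{xyzPath}, invisibly.
#' @export
writeConformers <- function(cs, mol, xyzPath, csvPath) {
  n <- nAtoms(mol)
  lines <- character()
  for (k in seq_along(cs@energies)) {
    X <- cs@geometries[[k]]
    lines <- c(lines, as.character(n),
               sprintf("conformer=%d energy=%s", k, fmtNum(cs@energies[k])),
               vapply(seq_len(n), function(i)
                 paste(mol@elements[i], fmtNum(X[i, 1L]), fmtNum(X[i, 2L]),
                       fmtNum(X[i, 3L])), character(1L)))
  }
  writeLines(lines, xyzPath)
  rank <- data.frame(rank = seq_along(cs@energies), energy = cs@energies)
  if (ncol(cs@torsions) > 0L) {
    tt <- as.data.frame(cs@torsions)
    names(tt) <- sprintf("torsion_%d", seq_len(ncol(cs@torsions)))
    rank <- cbind(rank, tt)
  }
  writeCsvFull(rank, csvPath)
  invisible(xyzPath)
}

ledgerRequired <- c("structure_id", "compound_id", "inter_model", "intra_model",
                    "E_inter", "E_adjustment", "dE_change_global",
                    "E_intra_global", "E_latt_global")

#' Read / write partition ledgers (CSV)
#'
#' Schema-validated round-trip-stable CSV I/O; unknown columns are preserved.
#' An empty file (header only) yields an empty ledger, not an error.
#'
#' @param path CSV path.
#' @return \code{readLedger}: a ledger data.frame.
#' @export
readLedger <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(ledgerRequired, names(df))
  if (length(miss))
    stop(sprintf("'%s' is missing required ledger column(s): %s", path,
                 paste(miss, collapse = ", ")))
  df
}

#' @rdname readLedger
#' @param ledger a ledger data.frame.
#' @export
writeLedger <- function(ledger, path) {
  miss <- setdiff(ledgerRequired, names(ledger))
  if (length(miss))
    stop("ledger is missing required column(s): ", paste(miss, collapse = ", "))
  writeCsvFull(ledger, path)
  invisible(path)
}

pairsRequired <- c("compound", "refcode_ref", "refcode_alt", "dH_exp", "subset")

#' Read / write polymorph pairing tables (CSV)
#'
#' The pairing table lists one row per polymorph pair: the experimentally
#' stable reference form, the alternative form, the experimental enthalpy
#' difference dH_exp (kJ/mol, alternative relative to reference, >= 0 by
#' convention) and a subset label. A dE_latt column (precomputed relative
#' lattice energies) and free-text columns are preserved when present.
#'
#' @param path CSV path.
#' @return \code{readPairs}: a pairing-table data.frame.
#' @export
readPairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(pairsRequired, names(df))
  if (length(miss))
    stop(sprintf("'%s' is missing required pairing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (nrow(df) && any(df$dH_exp < 0))
    stop("dH_exp must be >= 0 (reference form is the experimentally stable one)")
  if (nrow(df) && any(df$refcode_ref == df$refcode_alt))
    stop("refcode_ref and refcode_alt must differ")
  df
}

#' @rdname readPairs
#' @param pairs a pairing-table data.frame.
#' @export
writePairs <- function(pairs, path) {
  miss <- setdiff(pairsRequired, names(pairs))
  if (length(miss))
    stop("pairing table is missing required column(s): ",
         paste(miss, collapse = ", "))
  writeCsvFull(pairs, path)
  invisible(path)
}

#' Write a run-provenance record (JSON)
#'
#' @param config named list of run configuration (inputs, models, settings).
#' @param path output .json path.
#' @param seed RNG seed recorded with the run.
#' @return \code{path}, invisibly.
#' @export
writeProvenance <- function(config, path, seed = NA_integer_) {
  rec <- list(config = config, seed = seed,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("LatticePartition")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Path to a packaged fixture
#'
#' @param name fixture file name under the package's extdata directory, e.g.
#'   \code{"table1.csv"} or \code{"fig4_worked_examples.csv"}.
#' @return the absolute file path.
#' @export
fixturePath <- function(name) {
  p <- system.file("extdata", name, package = "LatticePartition")
  if (!nzchar(p)) stop(sprintf("no packaged fixture '%s'", name))
  p
}
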