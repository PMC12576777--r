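## User-facing constructors and accessors.

#' Construct a Molecule
#'
#' Builds a \linkS4class{Molecule} from elements, coordinates, a bond list and
#' force-field parameters. Angle and torsion lists are derived automatically
#' from the bond connectivity when not supplied; the nonbonded 1-2/1-3
#' exclusion and 1-4 scaling matrix is precomputed.
#'
#' @param elements character vector of element symbols.
#' @param coords N x 3 numeric matrix of Cartesian coordinates (A).
#' @param bonds B x 2 matrix of 1-based atom indices.
#' @param bondPars B x 2 matrix (or length-2 vector recycled) with columns
#'   kb (kJ/mol/A^2) and r0 (A).
#' @param anglePars A x 2 matrix (or length-2 vector recycled) with columns
#'   ka (kJ/mol/rad^2) and theta0 (rad).
#' @param torsionPars either a list with one data.frame (columns V, n, gamma)
#'   per torsion, or a single data.frame recycled over all torsions.
#' @param charges per-atom partial charges (e), recycled.
#' @param sigma,epsilon per-atom Lennard-Jones parameters (A, kJ/mol), recycled.
#' @param angles,torsions optional explicit angle/torsion index matrices.
#' @param rotatable integer indices of rotatable torsion rows.
#' @param scale14 1-4 nonbonded scale factor (standard convention 0.5).
#' @param compoundId compound identifier.
#' @return a validated \linkS4class{Molecule}.
#' @export
Molecule <- function(elements, coords, bonds,
                     bondPars = c(1000, 1.54),
                     anglePars = c(300, 109.47 * pi / 180),
                     torsionPars = list(),
                     charges = 0, sigma = 3.4, epsilon = 0.5,
                     angles = NULL, torsions = NULL, rotatable = integer(),
                     scale14 = 0.5, compoundId = "compound") {
  n <- length(elements)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (is.null(angles)) angles <- deriveAngles(n, bonds)
  if (is.null(torsions)) torsions <- deriveTorsions(n, bonds)
  angles <- matrix(as.integer(angles), ncol = 3L)
  torsions <- matrix(as.integer(torsions), ncol = 4L)
  if (!is.matrix(bondPars))
    bondPars <- matrix(rep(bondPars, length.out = 2L * nrow(bonds)),
                       ncol = 2L, byrow = TRUE)
  if (!is.matrix(anglePars))
    anglePars <- matrix(rep(anglePars, length.out = 2L * nrow(angles)),
                        ncol = 2L, byrow = TRUE)
  if (is.data.frame(torsionPars))
    torsionPars <- rep(list(torsionPars), nrow(torsions))
  if (length(torsionPars) == 0L)
    torsionPars <- rep(list(data.frame(V = 0, n = 1, gamma = 0)),
                       nrow(torsions))
  charges <- rep(charges, length.out = n)
  sigma <- rep(sigma, length.out = n)
  epsilon <- rep(epsilon, length.out = n)
  D <- graphDistances(n, bonds, maxd = 3L)
  pairScale <- matrix(1, n, n)
  pairScale[D <= 2] <- 0
  pairScale[D == 3] <- scale14
  diag(pairScale) <- 0
  new("Molecule", elements = elements, coords = coords, charges = charges,
      bonds = bonds, angles = angles, torsions = torsions,
      rotatable = as.integer(rotatable), bondPars = bondPars,
      anglePars = anglePars, torsionPars = torsionPars,
      sigma = sigma, epsilon = epsilon, pairScale = pairScale,
      compoundId = compoundId)
}

deriveAngles <- function(n, bonds) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2L)
      for (c0 in seq_len(ncol(cmb)))
        out[[length(out) + 1L]] <- c(cmb[1L, c0], j, cmb[2L, c0])
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 3L))
  do.call(rbind, out)
}

deriveTorsions <- function(n, bonds) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1L]; j <- bonds[b, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1L]; k <- bonds[b, 2L]
    for (i in setdiff(adj[[j]], k))
      for (l in setdiff(adj[[k]], j))
        if (i != l) out[[length(out) + 1L]] <- c(i, j, k, l)
  }
  if (!length(out)) return(matrix(integer(), ncol = 4L))
  ## one quadruple per central bond keeps the torsion energy unambiguous for
  ## acyclic chain molecules
  m <- do.call(rbind, out)
  key <- paste(pmin(m[, 2L], m[, 3L]), pmax(m[, 2L], m[, 3L]))
  m[!duplicated(key), , drop = FALSE]
}

#' Construct a CrystalStructure
#'
#' @param lattice 3 x 3 matrix of lattice vectors (rows, A).
#' @param molecule shared \linkS4class{Molecule} template.
#' @param coordsList list of N x 3 coordinate matrices, one per molecule in the
#'   cell (or a single matrix for Z = 1).
#' @param structureId,compoundId identifiers.
#' @return a validated \linkS4class{CrystalStructure}.
#' @export
CrystalStructure <- function(lattice, molecule, coordsList,
                             structureId = "XTAL", compoundId = compoundId0(molecule)) {
  if (is.matrix(coordsList)) coordsList <- list(coordsList)
  lattice <- as.matrix(lattice)
  storage.mode(lattice) <- "double"
  new("CrystalStructure", lattice = lattice, molecule = molecule,
      coordsList = lapply(coordsList, function(x) {
        x <- as.matrix(x); storage.mode(x) <- "double"; x
      }),
      structureId = structureId, compoundId = compoundId)
}

compoundId0 <- function(mol) mol@compoundId

#' Construct a ForceFieldConfig
#'
#' @param cutoff intermolecular cutoff (A); the periodic sum runs over all
#'   lattice images within the cutoff and both Lennard-Jones and Coulomb terms
#'   are potential-shifted to vanish at it.
#' @param coulombK Coulomb constant (kJ/mol A e^-2).
#' @param scale14 1-4 intramolecular nonbonded scale factor.
#' @param forceTol optimizer tolerance on the maximum force component
#'   (kJ/mol/A).
#' @param maxIter maximum optimizer iterations.
#' @param cellMode "fixed" (default) or "isotropic" cell relaxation.
#' @return a \linkS4class{ForceFieldConfig}.
#' @export
ForceFieldConfig <- function(cutoff = 12, coulombK = 1389.35458,
                             scale14 = 0.5, forceTol = 1e-3,
                             maxIter = 500L, cellMode = c("fixed", "isotropic")) {
  cellMode <- match.arg(cellMode)
  new("ForceFieldConfig", cutoff = cutoff, coulombK = coulombK,
      scale14 = scale14, forceTol = forceTol, maxIter = as.integer(maxIter),
      cellMode = cellMode)
}

#' Construct a BackendEnergies record
#'
#' @param crystalPerMolecule,gasSP,gasOpt,gasGlobalMin the four reference-state
#'   energies in kJ/mol.
#' @param backend backend label.
#' @return a validated \linkS4class{BackendEnergies}.
#' @export
BackendEnergies <- function(crystalPerMolecule, gasSP, gasOpt, gasGlobalMin,
                            backend = "toy-ff") {
  new("BackendEnergies", crystalPerMolecule = crystalPerMolecule,
      gasSP = gasSP, gasOpt = gasOpt, gasGlobalMin = gasGlobalMin,
      backend = backend)
}

## -- accessors --------------------------------------------------------------

#' @describeIn Molecule number of atoms.
#' @param x a Molecule.
#' @export
setMethod("nAtoms", "Molecule", function(x) length(x@elements))

#' @describeIn Molecule number of rotatable bonds.
#' @export
setMethod("nRotatableBonds", "Molecule", function(x) length(x@rotatable))

#' @export
setMethod("compoundId", "Molecule", function(x) x@compoundId)

#' @export
setMethod("compoundId", "CrystalStructure", function(x) x@compoundId)

#' @export
setMethod("compoundId", "EnergyPartition", function(x) x@compoundId)

#' @export
setMethod("structureId", "CrystalStructure", function(x) x@structureId)

#' @export
setMethod("structureId", "EnergyPartition", function(x) x@structureId)

#' @param x object with coordinates.
#' @param ... for CrystalStructure, \code{molecule} selects the molecule index.
#' @export
setMethod("coordinates", "Molecule", function(x, ...) x@coords)

#' @export
setMethod("coordinates", "CrystalStructure", function(x, molecule = 1L, ...)
  x@coordsList[[molecule]])

#' @export
setMethod("latticeVectors", "CrystalStructure", function(x) x@lattice)

#' @export
setMethod("zMolecules", "CrystalStructure", function(x) length(x@coordsList))

#' @export
setMethod("energies", "ConformerSet", function(x) x@energies)

#' @export
setMethod("eInter", "EnergyPartition", function(x) x@eInter)

#' @export
setMethod("eAdjustment", "EnergyPartition", function(x) x@eAdjustment)

#' @export
setMethod("dEChangeGlobal", "EnergyPartition", function(x) x@dEChangeGlobal)

#' @export
setMethod("eIntraGlobal", "EnergyPartition", function(x) x@eIntraGlobal)

#' @export
setMethod("eLattGlobal", "EnergyPartition", function(x) x@eLattGlobal)
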