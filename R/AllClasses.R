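## S4 classes for the lattice-energy partition machinery.

#' Molecule: geometry, topology and force-field parameters
#'
#' A single flexible molecule: element symbols, Cartesian coordinates in
#' Angstrom, partial charges in units of e, a bonded topology (bonds, angles,
#' torsion quadruples, the rotatable-torsion subset) and per-term classical
#' force-field parameters. Harmonic bonds and angles, a cosine torsion series
#' \eqn{\sum_n (V_n/2)(1 + \cos(n\phi - \gamma))}, and per-atom Lennard-Jones
#' \eqn{\sigma}/\eqn{\epsilon} with Lorentz-Berthelot combination. Nonbonded
#' intramolecular pairs separated by one or two bonds are excluded, 1-4 pairs
#' are scaled (the scale matrix is precomputed in \code{pairScale}).
#'
#' @slot elements character vector of element symbols.
#' @slot coords numeric N x 3 matrix, Cartesian Angstrom.
#' @slot charges numeric partial charges (e).
#' @slot bonds integer B x 2 matrix of 1-based atom index pairs.
#' @slot angles integer A x 3 matrix (i-j-k, vertex j).
#' @slot torsions integer T x 4 matrix of bonded paths i-j-k-l.
#' @slot rotatable integer indices into torsion rows marking rotatable bonds.
#' @slot bondPars numeric B x 2 matrix, columns kb (kJ/mol/A^2) and r0 (A).
#' @slot anglePars numeric A x 2 matrix, columns ka (kJ/mol/rad^2), theta0 (rad).
#' @slot torsionPars list of data.frames with columns V (kJ/mol), n, gamma (rad),
#'   one per torsion row.
#' @slot sigma,epsilon per-atom Lennard-Jones parameters (A, kJ/mol).
#' @slot pairScale numeric N x N nonbonded scale matrix (0, 0.5 or 1).
#' @slot compoundId character compound identifier.
#' @exportClass Molecule
setClass("Molecule", representation(
  elements = "character",
  coords = "matrix",
  charges = "numeric",
  bonds = "matrix",
  angles = "matrix",
  torsions = "matrix",
  rotatable = "integer",
  bondPars = "matrix",
  anglePars = "matrix",
  torsionPars = "list",
  sigma = "numeric",
  epsilon = "numeric",
  pairScale = "matrix",
  compoundId = "character"
))

setValidity("Molecule", function(object) {
  n <- length(object@elements)
  msg <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n)
    msg <- c(msg, "'coords' must be an N x 3 numeric matrix matching 'elements'")
  if (length(object@charges) != n) msg <- c(msg, "'charges' length mismatch")
  if (length(object@sigma) != n || length(object@epsilon) != n)
    msg <- c(msg, "per-atom LJ parameter length mismatch")
  if (nrow(object@bonds) != nrow(object@bondPars))
    msg <- c(msg, "'bondPars' must have one row per bond")
  if (nrow(object@angles) != nrow(object@anglePars))
    msg <- c(msg, "'anglePars' must have one row per angle")
  if (nrow(object@torsions) != length(object@torsionPars))
    msg <- c(msg, "'torsionPars' must have one entry per torsion")
  if (length(msg)) return(msg)
  if (n > 1L && !isConnectedGraph(n, object@bonds))
    msg <- c(msg, "bond graph is not connected")
  if (nrow(object@torsions)) {
    bkey <- apply(object@bonds, 1L, function(b) paste(sort(b), collapse = "-"))
    ok <- apply(object@torsions, 1L, function(t) {
      all(c(paste(sort(t[1:2]), collapse = "-"),
            paste(sort(t[2:3]), collapse = "-"),
            paste(sort(t[3:4]), collapse = "-")) %in% bkey)
    })
    if (!all(ok)) msg <- c(msg, "every torsion quadruple must be a bonded path")
  }
  if (length(object@rotatable) &&
      (any(object@rotatable < 1L) || any(object@rotatable > nrow(object@torsions))))
    msg <- c(msg, "'rotatable' indices out of torsion range")
  if (length(msg)) msg else TRUE
})

#' CrystalStructure: a periodic molecular crystal model
#'
#' Lattice vectors (rows of a 3 x 3 matrix, Angstrom) plus Z whole molecules
#' given as Cartesian coordinate matrices. All molecules share one
#' \linkS4class{Molecule} topology/parameter template (single-component
#' neutral crystals).
#'
#' @slot lattice numeric 3 x 3 matrix, one lattice vector per row (A).
#' @slot molecule the shared \linkS4class{Molecule} template.
#' @slot coordsList list of N x 3 coordinate matrices, one per molecule.
#' @slot structureId refcode-like structure identifier.
#' @slot compoundId compound identifier.
#' @exportClass CrystalStructure
setClass("CrystalStructure", representation(
  lattice = "matrix",
  molecule = "Molecule",
  coordsList = "list",
  structureId = "character",
  compoundId = "character"
))

setValidity("CrystalStructure", function(object) {
  msg <- character()
  L <- object@lattice
  if (!is.numeric(L) || !all(dim(L) == c(3L, 3L)))
    msg <- c(msg, "'lattice' must be a numeric 3 x 3 matrix")
  else if (abs(det(L)) <= 0)
    msg <- c(msg, "cell volume must be positive")
  if (length(object@coordsList) < 1L)
    msg <- c(msg, "Z must be >= 1")
  n <- length(object@molecule@elements)
  for (m in seq_along(object@coordsList)) {
    xm <- object@coordsList[[m]]
    if (!is.numeric(xm) || !all(dim(xm) == c(n, 3L))) {
      msg <- c(msg, sprintf("molecule %d coordinates are not %d x 3", m, n))
      next
    }
    bp <- object@molecule@bondPars
    if (nrow(bp)) {
      ## molecules may be stored wrapped across the periodic boundary; the
      ## sanity check applies to the re-wrapped (whole) geometry
      xw <- tryCatch(reWrapMolecule(xm, object@molecule, object@lattice),
                     error = function(e) xm)
      b <- object@molecule@bonds
      d <- sqrt(rowSums((xw[b[, 1L], , drop = FALSE] -
                           xw[b[, 2L], , drop = FALSE])^2))
      if (any(abs(d - bp[, 2L]) > 0.5 * bp[, 2L]))
        msg <- c(msg, sprintf(
          "molecule %d has bond lengths deviating >50%% from r0 (broken molecule?)", m))
    }
  }
  if (length(msg)) msg else TRUE
})

#' BackendEnergies: the four reference-state energies of a partition
#'
#' Per-molecule electronic (here: classical) energies in kJ/mol for one crystal
#' structure: the crystal itself, the single point of the extracted crystal
#' conformation in isolation, its nearest gas-phase local minimum, and the
#' global-minimum gas-phase conformer.
#'
#' @slot crystalPerMolecule crystal energy per molecule (kJ/mol).
#' @slot gasSP gas-phase single point of the crystal conformation.
#' @slot gasOpt nearest gas-phase local minimum of that conformation.
#' @slot gasGlobalMin global-minimum gas-phase conformer energy.
#' @slot backend label of the producing energy backend.
#' @exportClass BackendEnergies
setClass("BackendEnergies", representation(
  crystalPerMolecule = "numeric",
  gasSP = "numeric",
  gasOpt = "numeric",
  gasGlobalMin = "numeric",
  backend = "character"
))

setValidity("BackendEnergies", function(object) {
  tol <- 1e-6
  msg <- character()
  for (s in c("crystalPerMolecule", "gasSP", "gasOpt", "gasGlobalMin"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  if (length(msg)) return(msg)
  if (object@gasOpt > object@gasSP + tol)
    msg <- c(msg, "gasOpt must not exceed gasSP (relaxation can only lower the energy)")
  if (object@gasGlobalMin > object@gasOpt + tol)
    msg <- c(msg, "gasGlobalMin must not exceed gasOpt")
  if (length(msg)) msg else TRUE
})

#' ForceFieldConfig: evaluation and optimizer settings
#'
#' @slot cutoff intermolecular cutoff (A); interactions use a shifted potential
#'   so the energy is continuous at the cutoff.
#' @slot coulombK Coulomb constant in kJ/mol * A / e^2.
#' @slot scale14 scale factor for 1-4 intramolecular nonbonded pairs.
#' @slot forceTol optimizer convergence threshold on the maximum force
#'   component (kJ/mol/A).
#' @slot maxIter maximum optimizer iterations.
#' @slot cellMode crystal relaxation mode, "fixed" or "isotropic".
#' @exportClass ForceFieldConfig
setClass("ForceFieldConfig", representation(
  cutoff = "numeric",
  coulombK = "numeric",
  scale14 = "numeric",
  forceTol = "numeric",
  maxIter = "integer",
  cellMode = "character"
))

setValidity("ForceFieldConfig", function(object) {
  msg <- character()
  if (object@cutoff <= 0) msg <- c(msg, "'cutoff' must be positive")
  if (!object@cellMode %in% c("fixed", "isotropic"))
    msg <- c(msg, "'cellMode' must be \"fixed\" or \"isotropic\"")
  if (object@forceTol <= 0) msg <- c(msg, "'forceTol' must be positive")
  if (object@maxIter < 1L) msg <- c(msg, "'maxIter' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' ConformerSet: ranked gas-phase conformers of one compound
#'
#' @slot torsions numeric matrix of rotatable-torsion angles (degrees), one row
#'   per retained conformer.
#' @slot geometries list of optimized N x 3 coordinate matrices.
#' @slot energies numeric optimized energies (kJ/mol), sorted ascending so the
#'   global minimum is row 1.
#' @slot settings list of search settings used.
#' @exportClass ConformerSet
setClass("ConformerSet", representation(
  torsions = "matrix",
  geometries = "list",
  energies = "numeric",
  settings = "list"
))

setValidity("ConformerSet", function(object) {
  msg <- character()
  k <- length(object@energies)
  if (k < 1L) msg <- c(msg, "conformer set must be non-empty")
  if (length(object@geometries) != k)
    msg <- c(msg, "'geometries' length must match 'energies'")
  if (k > 1L && is.unsorted(object@energies))
    msg <- c(msg, "'energies' must be sorted ascending")
  if (k >= 1L && nrow(object@torsions) != k)
    msg <- c(msg, "'torsions' must have one row per conformer")
  if (length(msg)) msg else TRUE
})

#' EnergyPartition: the lattice-energy ledger of one crystal structure
#'
#' Holds the partition E_latt-global = E_inter + E_intra-global with
#' E_intra-global = E_adjustment + dE_change-global. Additivity is enforced to
#' 1e-9 kJ/mol and both intramolecular components must be non-negative up to
#' the optimizer noise floor (1e-6 kJ/mol).
#'
#' @slot structureId,compoundId identifiers.
#' @slot eInter intermolecular energy (kJ/mol), negative for bound crystals.
#' @slot eAdjustment conformational adjustment (strain) energy (kJ/mol).
#' @slot dEChangeGlobal global change energy (kJ/mol).
#' @slot eIntraGlobal total intramolecular penalty (kJ/mol).
#' @slot eLattGlobal global lattice energy (kJ/mol).
#' @slot interModel,intraModel labels of the energy models used for the
#'   intermolecular and intramolecular components.
#' @exportClass EnergyPartition
setClass("EnergyPartition", representation(
  structureId = "character",
  compoundId = "character",
  eInter = "numeric",
  eAdjustment = "numeric",
  dEChangeGlobal = "numeric",
  eIntraGlobal = "numeric",
  eLattGlobal = "numeric",
  interModel = "character",
  intraModel = "character"
))

setValidity("EnergyPartition", function(object) {
  addTol <- 1e-9
  negTol <- 1e-6
  msg <- character()
  vals <- c(object@eInter, object@eAdjustment, object@dEChangeGlobal,
            object@eIntraGlobal, object@eLattGlobal)
  if (!all(is.finite(vals)))
    msg <- c(msg, "all energy components must be finite")
  if (length(msg)) return(msg)
  if (abs(object@eIntraGlobal -
          (object@eAdjustment + object@dEChangeGlobal)) > addTol)
    msg <- c(msg, "eIntraGlobal must equal eAdjustment + dEChangeGlobal")
  if (abs(object@eLattGlobal - (object@eInter + object@eIntraGlobal)) > addTol)
    msg <- c(msg, "eLattGlobal must equal eInter + eIntraGlobal")
  if (object@eAdjustment < -negTol)
    msg <- c(msg, "eAdjustment must be >= 0 (adjustment energies are a penalty)")
  if (object@dEChangeGlobal < -negTol)
    msg <- c(msg, "dEChangeGlobal must be >= 0 (global minimum reference)")
  if (length(msg)) msg else TRUE
})

#' EnvelopeFit: upper-envelope estimate of the intra-to-inter ratio bound
#'
#' @slot estimator "max-ratio" or "upper-quantile".
#' @slot slope estimated envelope slope s in |E_intra-global| <= s * |E_inter|.
#' @slot n number of ratio records fitted.
#' @slot level quantile level (NA for the max-ratio estimator).
#' @exportClass EnvelopeFit
setClass("EnvelopeFit", representation(
  estimator = "character",
  slope = "numeric",
  n = "integer",
  level = "numeric"
))

setValidity("EnvelopeFit", function(object) {
  if (length(object@slope) != 1L || !is.finite(object@slope) || object@slope < 0)
    return("'slope' must be a single non-negative number")
  TRUE
})

## -- show methods -----------------------------------------------------------

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d atoms, %d bonds, %d torsions (%d rotatable)\n",
              object@compoundId, length(object@elements), nrow(object@bonds),
              nrow(object@torsions), length(object@rotatable)))
})

setMethod("show", "CrystalStructure", function(object) {
  v <- abs(det(object@lattice))
  cat(sprintf("CrystalStructure '%s' (%s): Z = %d, cell volume %.2f A^3\n",
              object@structureId, object@compoundId,
              length(object@coordsList), v))
})

setMethod("show", "BackendEnergies", function(object) {
  cat(sprintf(
    "BackendEnergies [%s] (kJ/mol):\n  crystal/molecule %.4f | gas SP %.4f | gas Opt %.4f | gas global min %.4f\n",
    object@backend, object@crystalPerMolecule, object@gasSP, object@gasOpt,
    object@gasGlobalMin))
})

setMethod("show", "ConformerSet", function(object) {
  cat(sprintf("ConformerSet: %d conformers, global minimum %.4f kJ/mol\n",
              length(object@energies), object@energies[1L]))
})

setMethod("show", "EnergyPartition", function(object) {
  cat(sprintf("EnergyPartition '%s' (%s) [inter: %s | intra: %s], kJ/mol\n",
              object@structureId, object@compoundId, object@interModel,
              object@intraModel))
  cat(sprintf("  E_inter        %10.3f\n", object@eInter))
  cat(sprintf("  E_adjustment   %10.3f\n", object@eAdjustment))
  cat(sprintf("  dE_change-glob %10.3f\n", object@dEChangeGlobal))
  cat(sprintf("  E_intra-global %10.3f\n", object@eIntraGlobal))
  cat(sprintf("  E_latt-global  %10.3f\n", object@eLattGlobal))
})

setMethod("show", "EnvelopeFit", function(object) {
  cat(sprintf("EnvelopeFit (%s%s): slope %.4f from %d records\n",
              object@estimator,
              if (is.finite(object@level)) sprintf(", level %.2f", object@level) else "",
              object@slope, object@n))
})
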