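## The core lattice-energy partition:
##   E_latt-global = E_inter + E_intra-global
##   E_intra-global = E_adjustment + dE_change-global
## with E_inter = E(crystal, per molecule) - E(crystal conformation, gas SP),
## E_adjustment = gas SP - gas Opt (nearest local minimum), and
## dE_change-global = gas Opt - gas Opt of the global-minimum conformer.

#' Extract a whole crystal conformation
#'
#' Returns the Cartesian geometry of one molecule of the crystal, re-wrapped by
#' bond connectivity so the molecule is whole even if its stored coordinates
#' straddle a periodic boundary.
#'
#' @param xtal a \linkS4class{CrystalStructure} (normally after relaxation).
#' @param molecule molecule index (1..Z).
#' @return an N x 3 coordinate matrix.
#' @export
extractCrystalConformation <- function(xtal, molecule = 1L) {
  Z <- zMolecules(xtal)
  if (molecule < 1L || molecule > Z)
    stop(sprintf("molecule index %d out of range 1..%d", molecule, Z))
  reWrapMolecule(coordinates(xtal, molecule = molecule), xtal@molecule,
                 latticeVectors(xtal))
}

#' Intermolecular energy of a crystal
#'
#' E_inter = crystal energy per molecule minus the mean gas-phase single point
#' of the extracted crystal conformation(s). The intramolecular terms cancel
#' exactly between the two evaluations, leaving the pure molecule-molecule
#' interaction energy; negative for bound crystals.
#'
#' @param xtal a relaxed \linkS4class{CrystalStructure}.
#' @param cfg a \linkS4class{ForceFieldConfig}.
#' @return E_inter in kJ/mol per molecule.
#' @export
computeInter <- function(xtal, cfg = ForceFieldConfig()) {
  eCrys <- crystalEnergyPerMolecule(xtal, cfg)
  gasSP <- vapply(seq_len(zMolecules(xtal)), function(m)
    moleculeEnergy(xtal@molecule, extractCrystalConformation(xtal, m), cfg),
    numeric(1L))
  eCrys - mean(gasSP)
}

#' Conformational adjustment (strain) energy
#'
#' The cost of distorting the nearest gas-phase conformer into the exact
#' crystal conformation: gas single point minus the energy after relaxing to
#' the nearest local minimum (no torsion jumps). Always non-negative up to the
#' optimizer noise floor.
#'
#' @param mol the \linkS4class{Molecule} topology.
#' @param conformation N x 3 crystal-conformation coordinates.
#' @param cfg a \linkS4class{ForceFieldConfig}.
#' @return list with \code{adjustment}, \code{gasSP}, \code{gasOpt},
#'   \code{optCoords}, \code{converged}.
#' @export
computeAdjustment <- function(mol, conformation, cfg = ForceFieldConfig()) {
  gasSP <- moleculeEnergy(mol, conformation, cfg)
  opt <- optimizeMolecule(mol, conformation, cfg)
  adj <- gasSP - opt$energy
  if (adj < -1e-6)
    stop(sprintf(
      "negative adjustment energy (%.3g kJ/mol): relaxation raised the energy", adj))
  list(adjustment = adj, gasSP = gasSP, gasOpt = opt$energy,
       optCoords = opt$coords, converged = opt$converged)
}

#' Global change energy
#'
#' Gap between the gas-phase conformer underlying the crystal conformation and
#' the global-minimum gas-phase conformer: gasOpt - gasGlobalMin. A negative
#' value beyond the tolerance signals that the conformer search missed the true
#' minimum and is raised as an error.
#'
#' @param gasOpt energy of the locally relaxed crystal conformer (kJ/mol).
#' @param gasGlobalMin global-minimum conformer energy from the same
#'   intramolecular backend (kJ/mol).
#' @param tol noise tolerance (kJ/mol).
#' @return dE_change-global in kJ/mol.
#' @export
computeChangeGlobal <- function(gasOpt, gasGlobalMin, tol = 1e-6) {
  d <- gasOpt - gasGlobalMin
  if (d < -tol)
    stop(sprintf(
      "dE_change-global = %.3g kJ/mol < 0: the conformer search returned a minimum above the relaxed crystal conformer; the global minimum was missed",
      d))
  d
}

#' Assemble an energy-partition ledger entry
#'
#' Builds a validated \linkS4class{EnergyPartition} from its independent
#' components; E_intra-global and E_latt-global are derived, so additivity
#' holds by construction and is re-checked by the class validity.
#'
#' @param eInter intermolecular energy (kJ/mol).
#' @param eAdjustment adjustment energy (kJ/mol, >= 0).
#' @param dEChangeGlobal global change energy (kJ/mol, >= 0).
#' @param structureId,compoundId identifiers.
#' @param interModel,intraModel energy-model labels; mixed-model partitions
#'   (different inter and intra backends) are first-class.
#' @return an \linkS4class{EnergyPartition}.
#' @export
assemblePartition <- function(eInter, eAdjustment, dEChangeGlobal,
                              structureId = "XTAL", compoundId = "compound",
                              interModel = "toy-ff", intraModel = interModel) {
  new("EnergyPartition", structureId = structureId, compoundId = compoundId,
      eInter = eInter, eAdjustment = eAdjustment,
      dEChangeGlobal = dEChangeGlobal,
      eIntraGlobal = eAdjustment + dEChangeGlobal,
      eLattGlobal = eInter + eAdjustment + dEChangeGlobal,
      interModel = interModel, intraModel = intraModel)
}

#' Run the full partition pipeline on one crystal
#'
#' Relax the crystal, extract the crystal conformation(s), compute E_inter, the
#' adjustment energy, run the conformer search (seeded with the observed
#' crystal conformations) and assemble the partition ledger. With Z > 1 the
#' intramolecular terms are averaged over the symmetry-independent molecules.
#'
#' @param xtal a \linkS4class{CrystalStructure} (raw; it is relaxed first).
#' @param cfg a \linkS4class{ForceFieldConfig}.
#' @param settings conformer-search settings.
#' @return an \linkS4class{EnergyPartition} with attributes
#'   \code{backendEnergies} (a \linkS4class{BackendEnergies}) and
#'   \code{intermediates} (per-stage log).
#' @export
runPartitionPipeline <- function(xtal, cfg = ForceFieldConfig(),
                                 settings = conformerSettings()) {
  sid <- structureId(xtal)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage '%s' failed: %s", sid, name,
                   conditionMessage(e)), call. = FALSE))
  }
  relaxed <- stage("optimize_crystal", optimizeCrystal(xtal, cfg))
  xt <- relaxed$crystal
  Z <- zMolecules(xt)
  confs <- stage("extract_conformation",
                 lapply(seq_len(Z), function(m) extractCrystalConformation(xt, m)))
  eCrys <- relaxed$energyPerMolecule
  adjs <- stage("adjustment",
                lapply(confs, function(x0) computeAdjustment(xt@molecule, x0, cfg)))
  gasSP <- mean(vapply(adjs, `[[`, numeric(1L), "gasSP"))
  gasOpt <- mean(vapply(adjs, `[[`, numeric(1L), "gasOpt"))
  eInter <- eCrys - gasSP
  eAdj <- gasSP - gasOpt
  cs <- stage("conformer_search",
              generateConformers(xt@molecule, settings, cfg,
                                 extraSeeds = confs))
  ## the relaxed crystal conformers are part of the candidate set, so the
  ## global minimum can never sit above them
  gasMin <- min(globalMinEnergy(cs),
                vapply(adjs, `[[`, numeric(1L), "gasOpt"))
  dChg <- stage("change_global", computeChangeGlobal(gasOpt, gasMin))
  p <- stage("assemble",
             assemblePartition(eInter, max(eAdj, 0), max(dChg, 0),
                               structureId = sid,
                               compoundId = compoundId(xt),
                               interModel = "toy-ff", intraModel = "toy-ff"))
  attr(p, "backendEnergies") <- BackendEnergies(eCrys, gasSP, gasOpt,
                                                min(gasMin, gasOpt),
                                                backend = "toy-ff")
  attr(p, "intermediates") <- list(
    crystalEnergyPerMolecule = eCrys, gasSP = gasSP, gasOpt = gasOpt,
    gasGlobalMin = gasMin, conformerEnergies = energies(cs),
    crystalConverged = relaxed$converged,
    adjustmentConverged = vapply(adjs, `[[`, logical(1L), "converged"))
  p
}

#' Collect EnergyPartition objects into a ledger data.frame
#'
#' @param partitions a list of \linkS4class{EnergyPartition} objects (or a
#'   single one).
#' @return a data.frame with the standard ledger columns (structure_id,
#'   compound_id, inter_model, intra_model, E_inter, E_adjustment,
#'   dE_change_global, E_intra_global, E_latt_global).
#' @export
partitionLedger <- function(partitions) {
  if (is(partitions, "EnergyPartition")) partitions <- list(partitions)
  do.call(rbind, lapply(partitions, function(p) data.frame(
    structure_id = structureId(p), compound_id = compoundId(p),
    inter_model = p@interModel, intra_model = p@intraModel,
    E_inter = eInter(p), E_adjustment = eAdjustment(p),
    dE_change_global = dEChangeGlobal(p), E_intra_global = eIntraGlobal(p),
    E_latt_global = eLattGlobal(p), stringsAsFactors = FALSE)))
}

#' Validate a partition ledger
#'
#' Checks the additivity identities and the non-negativity of the
#' intramolecular components on every row.
#'
#' @param ledger a ledger data.frame.
#' @param addTol additivity tolerance (kJ/mol).
#' @param negTol non-negativity tolerance (kJ/mol).
#' @return the ledger, invisibly; errors name the offending structure ids.
#' @export
validateLedger <- function(ledger, addTol = 1e-9, negTol = 1e-6) {
  req <- c("structure_id", "E_inter", "E_adjustment", "dE_change_global",
           "E_intra_global", "E_latt_global")
  miss <- setdiff(req, names(ledger))
  if (length(miss))
    stop("ledger is missing required column(s): ", paste(miss, collapse = ", "))
  bad1 <- abs(ledger$E_intra_global -
                (ledger$E_adjustment + ledger$dE_change_global)) > addTol
  bad2 <- abs(ledger$E_latt_global -
                (ledger$E_inter + ledger$E_intra_global)) > addTol
  bad3 <- ledger$E_adjustment < -negTol | ledger$dE_change_global < -negTol
  bad <- bad1 | bad2 | bad3
  if (any(bad))
    stop("ledger invariant violations for: ",
         paste(ledger$structure_id[bad], collapse = ", "))
  invisible(ledger)
}
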