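## Generics. Accessors are preferred over direct slot access throughout.

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @export
setGeneric("nRotatableBonds", function(x) standardGeneric("nRotatableBonds"))

#' @export
setGeneric("compoundId", function(x) standardGeneric("compoundId"))

#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @export
setGeneric("coordinates", function(x, ...) standardGeneric("coordinates"))

#' @export
setGeneric("latticeVectors", function(x) standardGeneric("latticeVectors"))

#' @export
setGeneric("zMolecules", function(x) standardGeneric("zMolecules"))

#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' Global-minimum conformer energy of a conformer set
#'
#' Returns the lowest optimized gas-phase conformer energy, the reference for
#' the global change energy.
#'
#' @param x a \linkS4class{ConformerSet}.
#' @return energy in kJ/mol.
#' @export
setGeneric("globalMinEnergy", function(x) standardGeneric("globalMinEnergy"))

#' @export
setGeneric("eInter", function(x) standardGeneric("eInter"))

#' @export
setGeneric("eAdjustment", function(x) standardGeneric("eAdjustment"))

#' @export
setGeneric("dEChangeGlobal", function(x) standardGeneric("dEChangeGlobal"))

#' @export
setGeneric("eIntraGlobal", function(x) standardGeneric("eIntraGlobal"))

#' @export
setGeneric("eLattGlobal", function(x) standardGeneric("eLattGlobal"))

#' Intra-to-intermolecular energy ratio of a partition
#'
#' Computes r = |E_intra-global / E_inter| together with its decomposition into
#' the adjustment share r_adj = |E_adjustment / E_inter| and the change share
#' r_chg = |dE_change-global / E_inter| (r = r_adj + r_chg since both
#' intramolecular components are non-negative).
#'
#' @param x an \linkS4class{EnergyPartition} or a partition ledger data.frame.
#' @param ... further arguments; \code{dataset} labels the records.
#' @return a data.frame with columns structure_id, dataset, r, r_adj, r_chg.
#' @export
setGeneric("ratio", function(x, ...) standardGeneric("ratio"))

#' Kink-site incorporation score
#'
#' Net stabilization gained by a molecule attaching at a kink (half-crystal)
#' site: \code{f * |E_inter| - E_intra_global} in kJ/mol, where \code{f} is the
#' fraction of the full set of lattice interactions engaged at the site
#' (default 0.5, the Kossel/Stranski half-crystal position). Positive values
#' mean kink incorporation is energetically favorable.
#'
#' @param x an \linkS4class{EnergyPartition}, or the intermolecular energy
#'   E_inter (kJ/mol, negative) when called with \code{eIntraGlobal}.
#' @param ... see methods: \code{eIntraGlobal}, \code{f}.
#' @return net stabilization in kJ/mol, with attribute \code{favorable}.
#' @export
setGeneric("kinkScore", function(x, ...) standardGeneric("kinkScore"))
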