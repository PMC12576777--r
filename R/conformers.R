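## Systematic rotatable-torsion conformer search: torsion-grid enumeration,
## energy ranking, local refinement of the top states, deduplication.

#' Conformer search settings
#'
#' @param gridStep torsion grid step in degrees (default 120).
#' @param maxGenerated cap on the number of grid states kept for ranking
#'   (default 200).
#' @param topK number of energy-ranked grid states refined by local
#'   optimization (default 5).
#' @param maxSampled hard cap on the enumerated grid size (default 1e6); a
#'   larger grid is a configuration error.
#' @param dedupEnergy,dedupTorsion duplicate thresholds: two conformers are the
#'   same when their energies differ by less than \code{dedupEnergy} kJ/mol and
#'   every rotatable torsion differs by less than \code{dedupTorsion} degrees.
#' @param nudge deterministic offset (degrees) added to grid torsions before
#'   refinement; breaks the symmetric saddle points that exact grid geometries
#'   of symmetric torsion potentials sit on.
#' @return a settings list.
#' @export
conformerSettings <- function(gridStep = 120, maxGenerated = 200L, topK = 5L,
                              maxSampled = 1e6, dedupEnergy = 0.01,
                              dedupTorsion = 15, nudge = 2) {
  list(gridStep = gridStep, maxGenerated = as.integer(maxGenerated),
       topK = as.integer(topK), maxSampled = maxSampled,
       dedupEnergy = dedupEnergy, dedupTorsion = dedupTorsion, nudge = nudge)
}

#' Generate gas-phase conformers by torsion-grid search
#'
#' Enumerates a regular grid over all rotatable torsions (plus the input
#' geometry's own torsion angles as a seed state), ranks the grid states by
#' pre-optimization energy, locally optimizes the \code{topK} lowest states,
#' removes duplicates and returns the conformers sorted by energy. For a rigid
#' molecule (no rotatable torsions) the single optimized geometry is returned.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param settings a list from \code{\link{conformerSettings}}.
#' @param cfg a \linkS4class{ForceFieldConfig}.
#' @param extraSeeds optional list of coordinate matrices used as additional
#'   starting states (e.g. observed crystal conformations).
#' @return a \linkS4class{ConformerSet}.
#' @export
generateConformers <- function(mol, settings = conformerSettings(),
                               cfg = ForceFieldConfig(), extraSeeds = list()) {
  nrot <- nRotatableBonds(mol)
  startCoords <- coordinates(mol)
  if (nrot == 0L) {
    opt <- optimizeMolecule(mol, startCoords, cfg)
    seeds <- c(list(opt), lapply(extraSeeds, function(x0)
      optimizeMolecule(mol, x0, cfg)))
    eo <- vapply(seeds, `[[`, numeric(1L), "energy")
    best <- which.min(eo)
    return(new("ConformerSet",
               torsions = matrix(numeric(), nrow = 1L, ncol = 0L),
               geometries = list(seeds[[best]]$coords),
               energies = seeds[[best]]$energy, settings = settings))
  }
  vals <- seq(0, 360 - settings$gridStep, by = settings$gridStep)
  ngrid <- length(vals)^nrot
  if (ngrid > settings$maxSampled)
    stop(sprintf(
      "torsion grid has %.3g states, above the sampling cap of %.3g; increase gridStep or enable coarser sampling",
      ngrid, settings$maxSampled))
  grid <- as.matrix(expand.grid(rep(list(vals), nrot)))
  grid <- rbind(grid, torsionValues(mol, startCoords))
  for (x0 in extraSeeds) grid <- rbind(grid, torsionValues(mol, x0))
  ## rank grid states by pre-optimization energy
  preE <- apply(grid, 1L, function(tv)
    moleculeEnergy(mol, setTorsionValues(mol, startCoords, tv), cfg))
  ord <- order(preE)
  keep <- ord[seq_len(min(length(ord), settings$maxGenerated))]
  refine <- keep[seq_len(min(length(keep), settings$topK))]
  opts <- lapply(refine, function(i) {
    x0 <- setTorsionValues(mol, startCoords, grid[i, ] + settings$nudge)
    optimizeMolecule(mol, x0, cfg)
  })
  ## extra seeds are refined as given (no torsion snapping): the observed
  ## conformation must be able to land in its own basin
  for (x0 in extraSeeds)
    opts[[length(opts) + 1L]] <- optimizeMolecule(mol, x0, cfg)
  en <- vapply(opts, `[[`, numeric(1L), "energy")
  tmat <- do.call(rbind, lapply(opts, function(o)
    torsionValues(mol, o$coords)))
  ord <- order(en, apply(round(tmat, 6L), 1L, paste, collapse = ","))
  en <- en[ord]
  tmat <- tmat[ord, , drop = FALSE]
  opts <- opts[ord]
  ## dedup: keep the first (lowest-energy, lexicographic tie-break) of each
  ## (energy, torsion-vector) equivalence class
  keepRow <- rep(TRUE, length(en))
  for (i in seq_along(en)) {
    if (!keepRow[i]) next
    for (j in seq_len(i - 1L)) {
      if (!keepRow[j]) next
      if (abs(en[i] - en[j]) < settings$dedupEnergy &&
          all(circDiffDeg(tmat[i, ], tmat[j, ]) < settings$dedupTorsion)) {
        keepRow[i] <- FALSE
        break
      }
    }
  }
  new("ConformerSet", torsions = tmat[keepRow, , drop = FALSE],
      geometries = lapply(opts[keepRow], `[[`, "coords"),
      energies = en[keepRow], settings = settings)
}

#' @describeIn globalMinEnergy minimum optimized energy of the set.
#' @export
setMethod("globalMinEnergy", "ConformerSet", function(x) {
  if (!length(x@energies)) stop("empty conformer set")
  x@energies[1L]
})
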