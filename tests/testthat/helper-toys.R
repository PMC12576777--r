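## Shared toy systems and independent oracles used across the suite.

## Single Lennard-Jones site on a simple-cubic lattice.
ljSiteCrystal <- function(a = 4, sigma = 3.4, epsilon = 1,
                          origin = c(0.3, 0.2, 0.1)) {
  m1 <- Molecule(elements = "X", coords = rbind(c(0, 0, 0)),
                 bonds = matrix(integer(), ncol = 2L),
                 sigma = sigma, epsilon = epsilon, charges = 0,
                 compoundId = "LJ1")
  CrystalStructure(diag(c(a, a, a)), m1, rbind(origin), structureId = "SC-LJ")
}

## Independent brute-force direct lattice sum for the shifted LJ + Coulomb
## potential: loops over every atom pair and every integer image with no
## vectorization or minimum-image logic shared with the implementation.
directSumOracle <- function(xtal, cfg, kmax = 8L) {
  mol <- xtal@molecule
  L <- latticeVectors(xtal)
  X <- do.call(rbind, xtal@coordsList)
  n <- nAtoms(mol)
  Z <- zMolecules(xtal)
  molIdx <- rep(seq_len(Z), each = n)
  sig <- rep(mol@sigma, Z); eps <- rep(mol@epsilon, Z)
  q <- rep(mol@charges, Z)
  rc <- cfg@cutoff
  e <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X)))
    for (n1 in -kmax:kmax) for (n2 in -kmax:kmax) for (n3 in -kmax:kmax) {
      t0 <- n1 * L[1L, ] + n2 * L[2L, ] + n3 * L[3L, ]
      if (all(c(n1, n2, n3) == 0L) && molIdx[i] == molIdx[j]) next
      r <- sqrt(sum((X[i, ] - X[j, ] + t0)^2))
      if (r >= rc || r < 1e-12) next
      s0 <- (sig[i] + sig[j]) / 2
      e0 <- sqrt(eps[i] * eps[j])
      s6 <- (s0 / r)^6; sc6 <- (s0 / rc)^6
      e <- e + 4 * e0 * (s6^2 - s6) - 4 * e0 * (sc6^2 - sc6) +
        cfg@coulombK * q[i] * q[j] * (1 / r - 1 / rc)
    }
  ## half for double-counted ordered pairs, normalized per molecule:
  ## the intermolecular lattice energy per molecule
  e / 2 / Z
}

## Closed-form cosine torsion series (kJ/mol), phi in degrees.
seriesEnergy <- function(pars, phiDeg) {
  phi <- phiDeg * pi / 180
  sum(pars$V / 2 * (1 + cos(pars$n * phi - pars$gamma)))
}

## Dense 1-D scan minimum of a torsion series (independent of the optimizer).
seriesScanMin <- function(pars, stepDeg = 0.01) {
  grid <- seq(0, 360 - stepDeg, by = stepDeg)
  e <- vapply(grid, function(p) seriesEnergy(pars, p), numeric(1L))
  list(phi = grid[which.min(e)], energy = min(e))
}

## A chain molecule with no intramolecular nonbonded terms (epsilon = 0), so
## the conformational energy is exactly the torsion series: closed-form
## oracles apply.
chainNoLJ <- function(chainLength = 4L,
                      torsionPars = data.frame(V = c(4, 12), n = c(1, 3),
                                               gamma = c(0, 0))) {
  buildChainMolecule(toyCompoundSpec(chainLength = chainLength,
                                     torsionPars = torsionPars, epsilon = 0))
}

## Small cached toy polymorph pair + its partition ledgers (built once; several
## test files exercise different facets of the same end-to-end run).
toyPairCache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- ForceFieldConfig(cutoff = 8)
      tp <- genToyPolymorphPair()
      pA <- runPartitionPipeline(tp$formA, cfg)
      pB <- runPartitionPipeline(tp$formB, cfg)
      cache <<- list(tp = tp, cfg = cfg, pA = pA, pB = pB)
    }
    cache
  }
})
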