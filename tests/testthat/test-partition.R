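## The partition ledger: reference-state arithmetic, worked-example values,
## pipeline contracts.

test_that("crystal conformations are extracted whole", {
  pair <- toyPairCache()
  rel <- optimizeCrystal(pair$tp$formB, pair$cfg)
  xt <- rel$crystal
  ## Z = 1: the unique molecule
  conf <- extractCrystalConformation(xt, 1L)
  expect_equal(dim(conf), c(4L, 3L))
  expect_error(extractCrystalConformation(xt, 5L), "out of range")
  ## a molecule stored straddling the boundary is re-wrapped: all toy-chain
  ## bonds shorter than 2 A afterwards
  xw <- coordinates(xt)
  xw[4, ] <- xw[4, ] + latticeVectors(xt)[2, ]
  xtw <- CrystalStructure(latticeVectors(xt), xt@molecule, list(xw),
                          structureId = "WRAP")
  confW <- extractCrystalConformation(xtw, 1L)
  d <- sqrt(rowSums((confW[xt@molecule@bonds[, 1L], ] -
                       confW[xt@molecule@bonds[, 2L], ])^2))
  expect_true(all(d < 2))
  ## cross-check: the extracted geometry's intramolecular energy equals the
  ## per-molecule intramolecular term of the crystal evaluation
  eIntra <- crystalEnergyPerMolecule(xt, pair$cfg) - computeInter(xt, pair$cfg)
  expect_equal(moleculeEnergy(xt@molecule, conf, pair$cfg), eIntra,
               tolerance = 1e-9)
})

test_that("E_inter is zero beyond the cutoff and matches the direct-sum oracle", {
  cfg <- ForceFieldConfig(cutoff = 12)
  mol <- buildChainMolecule(toyCompoundSpec())
  far <- CrystalStructure(diag(c(100, 100, 100)), mol, coordinates(mol),
                          structureId = "FAR")
  expect_identical(computeInter(far, cfg), 0)
  ## two-molecule LJ crystal: E_inter equals the intermolecular direct sum
  pair <- toyPairCache()
  xtB <- pair$tp$formB
  eInter <- computeInter(xtB, pair$cfg)
  oracle <- directSumOracle(xtB, pair$cfg)
  expect_equal(eInter, oracle, tolerance = 1e-8)
  expect_lt(eInter, 0)
  ## invariant under rigid translation of the whole crystal content
  xtT <- CrystalStructure(latticeVectors(xtB), xtB@molecule,
                          list(coordinates(xtB) +
                                 matrix(c(1.1, -0.7, 0.3), 4L, 3L, byrow = TRUE)),
                          structureId = "TR")
  expect_equal(computeInter(xtT, pair$cfg), eInter, tolerance = 1e-9)
})

test_that("adjustment energy matches the closed-form series difference and is non-negative", {
  cfg <- ForceFieldConfig()
  mol <- chainNoLJ()
  opt <- optimizeMolecule(mol, setTorsionValues(mol, coordinates(mol), 180), cfg)
  ## at a local minimum the adjustment is zero
  adj0 <- computeAdjustment(mol, opt$coords, cfg)
  expect_equal(adj0$adjustment, 0, tolerance = 1e-6)
  ## 20-degree distortion from the anti minimum: analytic series difference
  pars <- data.frame(V = c(4, 12), n = c(1, 3), gamma = c(0, 0))
  x160 <- setTorsionValues(mol, opt$coords, 160)
  adj <- computeAdjustment(mol, x160, cfg)
  expect_equal(adj$adjustment, seriesEnergy(pars, 160) - seriesEnergy(pars, 180),
               tolerance = 1e-5)
  expect_gte(adj$adjustment, -1e-6)
})

test_that("global change energy is the gauche-anti gap and rejects a missed minimum", {
  cfg <- ForceFieldConfig()
  mol <- chainNoLJ()
  pars <- data.frame(V = c(4, 12), n = c(1, 3), gamma = c(0, 0))
  gauche <- optimizeMolecule(mol, setTorsionValues(mol, coordinates(mol), 60), cfg)
  cs <- generateConformers(mol, cfg = cfg)
  dchg <- computeChangeGlobal(gauche$energy, globalMinEnergy(cs))
  ## analytic gap: series minimum near 60 vs the anti zero
  gaucheOracle <- local({
    grid <- seq(20, 100, by = 0.01)
    min(vapply(grid, function(p) seriesEnergy(pars, p), numeric(1L)))
  })
  expect_equal(dchg, gaucheOracle, tolerance = 1e-5)
  ## crystal conformer relaxing into the global basin gives zero
  anti <- optimizeMolecule(mol, coordinates(mol), cfg)
  expect_equal(computeChangeGlobal(anti$energy, globalMinEnergy(cs)), 0,
               tolerance = 1e-6)
  ## a negative gap beyond tolerance signals a missed global minimum
  expect_error(computeChangeGlobal(0, 1), "missed")
})

test_that("assemblePartition reproduces the published worked examples", {
  ## o-acetamidobenzamide alpha: E_inter -146.9, E_intra 15 -> E_latt ~ -132
  alpha <- assemblePartition(-146.9, 15, 0, structureId = "ACBNZA02",
                             compoundId = "ACBNZA")
  expect_equal(eLattGlobal(alpha), -131.9, tolerance = 1e-12)
  expect_equal(round(eLattGlobal(alpha)), -132)
  ## beta: E_inter -205.3 with E_intra 70.9 -> E_latt -134.4,
  ## 2.5 kJ/mol below the alpha form
  beta <- assemblePartition(-205.3, 70.9, 0, structureId = "ACBNZA01",
                            compoundId = "ACBNZA")
  expect_equal(eLattGlobal(beta), -134.4, tolerance = 1e-12)
  expect_equal(eLattGlobal(alpha) - eLattGlobal(beta), 2.5, tolerance = 1e-12)
  ## all-zero components give an all-zero ledger
  z <- assemblePartition(0, 0, 0)
  expect_identical(c(eInter(z), eIntraGlobal(z), eLattGlobal(z)), c(0, 0, 0))
  ## invariants enforced at construction
  expect_error(assemblePartition(-100, -5, 0), "eAdjustment")
  expect_error(assemblePartition(-100, 5, -1), "dEChangeGlobal")
})

test_that("the pipeline ledger satisfies additivity and rigid crystals have no intra penalty", {
  pair <- toyPairCache()
  for (p in list(pair$pA, pair$pB)) {
    expect_equal(eIntraGlobal(p), eAdjustment(p) + dEChangeGlobal(p),
                 tolerance = 1e-9)
    expect_equal(eLattGlobal(p), eInter(p) + eIntraGlobal(p), tolerance = 1e-9)
    expect_gte(eAdjustment(p), -1e-6)
    expect_gte(dEChangeGlobal(p), -1e-6)
  }
  ## rigid 3-atom toy: E_adjustment = dE_change = 0, E_latt = E_inter
  cfg <- ForceFieldConfig(cutoff = 8)
  rigid <- genToyPolymorphPair(toyCompoundSpec(chainLength = 3L))
  pr <- runPartitionPipeline(rigid$formB, cfg)
  expect_equal(eIntraGlobal(pr), 0, tolerance = 0.05)
  expect_equal(eLattGlobal(pr), eInter(pr), tolerance = 0.05)
})

test_that("the end-to-end toy polymorph pair shows the strained-conformer trade-off deterministically", {
  pair <- toyPairCache()
  pA <- pair$pA; pB <- pair$pB
  ## strained polymorph: larger intramolecular penalty AND better packing
  expect_gt(eIntraGlobal(pB), eIntraGlobal(pA))
  expect_lt(eInter(pB), eInter(pA))
  ## re-running the pipeline reproduces the ledger bit for bit
  pB2 <- runPartitionPipeline(pair$tp$formB, pair$cfg)
  expect_identical(partitionLedger(pB), partitionLedger(pB2))
  ## the ledger passes full validation
  led <- partitionLedger(list(pA, pB))
  expect_silent(validateLedger(led))
  expect_error(validateLedger(transform(led, E_latt_global = E_latt_global + 1)),
               "invariant")
})

test_that("backend-swap separability: the intra model never touches E_inter", {
  ## mixed-model partitions are first-class: swapping the intramolecular
  ## component changes the intra terms only
  p1 <- assemblePartition(-205.3, 60, 10.9, interModel = "inter-A",
                          intraModel = "intra-1")
  p2 <- assemblePartition(-205.3, 50, 20.9, interModel = "inter-A",
                          intraModel = "intra-2")
  expect_identical(eInter(p1), eInter(p2))
  expect_false(identical(eAdjustment(p1), eAdjustment(p2)))
  expect_identical(eIntraGlobal(p1), eIntraGlobal(p2))
  ## conformer equal to the global minimum: E_intra_global = E_adjustment
  p3 <- assemblePartition(-150, 12.5, 0)
  expect_identical(eIntraGlobal(p3), eAdjustment(p3))
})
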