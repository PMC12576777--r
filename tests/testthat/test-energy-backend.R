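## Toy force-field backend: analytic term values, periodic lattice sums against
## a brute-force oracle, and optimizer contracts.

test_that("bonded terms reproduce their closed forms", {
  ## harmonic diatomic at r0 is the energy zero
  dia <- Molecule(elements = c("C", "C"),
                  coords = rbind(c(0, 0, 0), c(1.54, 0, 0)),
                  bonds = rbind(c(1L, 2L)), bondPars = c(1000, 1.54),
                  epsilon = 0, charges = 0)
  expect_equal(moleculeEnergy(dia), 0)
  ## displaced diatomic: kb * (r - r0)^2
  dia2 <- Molecule(elements = c("C", "C"),
                   coords = rbind(c(0, 0, 0), c(1.64, 0, 0)),
                   bonds = rbind(c(1L, 2L)), bondPars = c(1000, 1.54),
                   epsilon = 0, charges = 0)
  expect_equal(moleculeEnergy(dia2), 1000 * 0.1^2, tolerance = 1e-10)

  ## 4-atom chain with a single 3-fold torsion {V3 = 5, n = 3, gamma = 0}:
  ## (V/2)(1 + cos 3 phi) gives 5 at phi = 0 and 0 at phi = 180
  mol <- chainNoLJ(torsionPars = data.frame(V = 5, n = 3, gamma = 0))
  x0 <- setTorsionValues(mol, coordinates(mol), 0)
  expect_equal(moleculeEnergy(mol, x0), 5.0, tolerance = 1e-8)
  x180 <- setTorsionValues(mol, coordinates(mol), 180)
  expect_equal(moleculeEnergy(mol, x180), 0.0, tolerance = 1e-8)
})

test_that("nonbonded pair at the LJ minimum distance gives -epsilon", {
  ## two unbonded sites cannot form one molecule; use a 1-4 pair with
  ## scale 1.0 and zero bonded parameters instead: pure LJ
  r <- 2^(1 / 6) * 3.4
  m1 <- Molecule(elements = "X", coords = rbind(c(0, 0, 0)),
                 bonds = matrix(integer(), ncol = 2L), sigma = 3.4,
                 epsilon = 2.5, charges = 0)
  big <- 200
  xt <- CrystalStructure(diag(c(big, big, big)), m1,
                         list(rbind(c(0, 0, 0)), rbind(c(r, 0, 0))),
                         structureId = "PAIR")
  cfg <- ForceFieldConfig(cutoff = 12)
  ## shifted potential: -eps - shift(rc), per molecule = half the pair energy
  s6c <- (3.4 / 12)^6
  shift <- 4 * 2.5 * (s6c^2 - s6c)
  expect_equal(crystalEnergyPerMolecule(xt, cfg), (-2.5 - shift) / 2,
               tolerance = 1e-10)
})

test_that("input validation rejects mismatched or non-finite coordinates", {
  mol <- chainNoLJ()
  expect_error(moleculeEnergy(mol, coordinates(mol)[1:3, ]), "4 x 3")
  bad <- coordinates(mol); bad[2, 2] <- NaN
  expect_error(moleculeEnergy(mol, bad), "non-finite")
})

test_that("periodic lattice sum matches the brute-force direct-sum oracle", {
  cfg <- ForceFieldConfig(cutoff = 12)
  ## single LJ site, simple cubic a = 4
  xt <- ljSiteCrystal(a = 4)
  expect_equal(crystalEnergyPerMolecule(xt, cfg), directSumOracle(xt, cfg),
               tolerance = 1e-10)
  ## two-molecule charged toy cell
  m1 <- Molecule(elements = "X", coords = rbind(c(0, 0, 0)),
                 bonds = matrix(integer(), ncol = 2L), sigma = 3.0,
                 epsilon = 0.8, charges = 0.05)
  xt2 <- CrystalStructure(diag(c(5, 6, 7)), m1,
                          list(rbind(c(0, 0, 0)), rbind(c(2.5, 3, 3.5))),
                          structureId = "TWO")
  cfg2 <- ForceFieldConfig(cutoff = 10)
  expect_equal(crystalEnergyPerMolecule(xt2, cfg2),
               directSumOracle(xt2, cfg2), tolerance = 1e-10)
  ## sanity: a clearly charged pair is dominated by the Coulomb repulsion
  expect_gt(crystalEnergyPerMolecule(xt2, cfg2), 0)
  ## 4-molecule chain crystal
  pair <- toyPairCache()
  xtB <- pair$tp$formB
  L <- latticeVectors(xtB)
  offs <- list(c(0, 0, 0), L[1, ], L[2, ], L[1, ] + L[2, ])
  cl4 <- lapply(offs, function(o)
    sweep(coordinates(xtB), 2L, -o))
  xt4 <- CrystalStructure(latticeVectors(xtB) * 2, xtB@molecule, cl4,
                          structureId = "FOUR")
  cfg3 <- ForceFieldConfig(cutoff = 8)
  ## the intermolecular part of the per-molecule energy matches the oracle
  intra4 <- mean(vapply(xt4@coordsList, function(xm)
    moleculeEnergy(xt4@molecule, xm, cfg3), numeric(1L)))
  expect_equal(crystalEnergyPerMolecule(xt4, cfg3) - intra4,
               directSumOracle(xt4, cfg3, kmax = 4L), tolerance = 1e-8)
})

test_that("per-molecule energy is invariant to lattice translations and supercells", {
  cfg <- ForceFieldConfig(cutoff = 12)
  xt <- ljSiteCrystal(a = 4)
  e0 <- crystalEnergyPerMolecule(xt, cfg)
  ## translate by an arbitrary combination of lattice vectors
  L <- latticeVectors(xt)
  shifted <- CrystalStructure(L, xt@molecule,
                              rbind(coordinates(xt) + 2 * L[1, ] - L[3, ]),
                              structureId = "SHIFT")
  expect_equal(crystalEnergyPerMolecule(shifted, cfg), e0, tolerance = 1e-8)
  ## 2 x 2 x 2 supercell replication
  offs <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cl <- lapply(seq_len(8L), function(i)
    rbind(coordinates(xt) + as.numeric(offs[i, ] %*% L)))
  super <- CrystalStructure(2 * L, xt@molecule, cl, structureId = "SUPER")
  expect_equal(crystalEnergyPerMolecule(super, cfg), e0, tolerance = 1e-8)
  ## isolated molecule in a huge cell: crystal energy equals the gas energy
  mol <- chainNoLJ()
  iso <- CrystalStructure(diag(c(100, 100, 100)), mol, coordinates(mol),
                          structureId = "ISO")
  expect_equal(crystalEnergyPerMolecule(iso, cfg), moleculeEnergy(mol),
               tolerance = 1e-12)
})

test_that("analytic gradient agrees with central differences", {
  mol <- buildChainMolecule(toyCompoundSpec(charges = c(0.05, -0.05)))
  x <- setTorsionValues(mol, coordinates(mol), 100)
  g <- LatticePartition:::moleculeGradient(mol, x)
  h <- 1e-6
  for (i in c(1L, 3L)) for (d in 1:3) {
    xp <- x; xp[i, d] <- xp[i, d] + h
    xm <- x; xm[i, d] <- xm[i, d] - h
    expect_equal(g[i, d], (moleculeEnergy(mol, xp) - moleculeEnergy(mol, xm)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("molecular optimizer descends monotonically to a gradient-tolerance minimum", {
  cfg <- ForceFieldConfig()
  mol <- chainNoLJ()
  ## started at a minimum: unchanged geometry, zero net energy change
  opt0 <- optimizeMolecule(mol, setTorsionValues(mol, coordinates(mol), 180), cfg)
  opt00 <- optimizeMolecule(mol, opt0$coords, cfg)
  expect_lt(max(abs(opt00$coords - opt0$coords)), 1e-4)
  expect_lt(abs(opt00$energy - opt0$energy), 1e-8)
  ## butane-like torsion from 150 degrees converges to the anti minimum
  x150 <- setTorsionValues(mol, coordinates(mol), 150)
  opt <- optimizeMolecule(mol, x150, cfg)
  oracle <- seriesScanMin(data.frame(V = c(4, 12), n = c(1, 3), gamma = c(0, 0)))
  expect_equal(torsionValues(mol, opt$coords), 180, tolerance = 0.5,
               ignore_attr = TRUE)
  expect_equal(opt$energy, oracle$energy, tolerance = 1e-6)
  ## contracts: monotone trace, gradient below tolerance
  expect_true(all(diff(opt$trace) <= 1e-12))
  expect_true(opt$converged)
  expect_lte(opt$maxForce, cfg@forceTol)
})

test_that("crystal relaxation recovers a displaced structure and never raises the energy", {
  pair <- toyPairCache()
  cfg <- pair$cfg
  rel <- optimizeCrystal(pair$tp$formB, cfg)
  expect_true(all(diff(rel$trace) <= 1e-12))
  ## already relaxed: unchanged
  rel2 <- optimizeCrystal(rel$crystal, cfg)
  expect_lt(abs(rel2$energyPerMolecule - rel$energyPerMolecule), 1e-8)
  ## displace one atom 0.3 A and recover the reference packing energy
  xd <- coordinates(rel$crystal)
  xd[2, ] <- xd[2, ] + c(0.3, 0, 0)
  xtd <- CrystalStructure(latticeVectors(rel$crystal), rel$crystal@molecule,
                          list(xd), structureId = "DISP")
  rel3 <- optimizeCrystal(xtd, cfg)
  expect_equal(rel3$energyPerMolecule, rel$energyPerMolecule, tolerance = 1e-6)
})
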