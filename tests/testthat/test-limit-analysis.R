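## 40%-limit machinery: ratio records, envelope estimators, cumulative
## fractions, component fits, kink scores, the crystallizability report.

workedExamples <- utils::read.csv(fixturePath("fig4_worked_examples.csv"),
                                  stringsAsFactors = FALSE)

test_that("ratio reproduces the published intra-to-inter fractions", {
  ## o-acetamidobenzamide beta: |70.9 / -205.3| ~ 0.35
  beta <- workedExamples[workedExamples$form == "beta", ]
  pBeta <- assemblePartition(beta$E_inter, beta$E_intra_global, 0,
                             structureId = beta$structure_id,
                             compoundId = beta$compound_id)
  expect_equal(round(ratio(pBeta)$r, 2), 0.35)
  ## ritonavir form II: |129 / -426| ~ 0.30
  rit2 <- workedExamples[workedExamples$form == "II", ]
  pRit <- assemblePartition(rit2$E_inter, rit2$E_intra_global, 0,
                            structureId = rit2$structure_id,
                            compoundId = rit2$compound_id)
  expect_equal(round(ratio(pRit)$r, 2), 0.30)
  ## a rigid molecule has ratio zero
  expect_equal(ratio(assemblePartition(-100, 0, 0))$r, 0)
  ## unbound crystals are rejected
  expect_error(ratio(assemblePartition(5, 1, 0)), "negative")
})

test_that("ratio decomposition is additive on every record", {
  led <- genEnergyTable(n = 500L, seed = 9L)
  rr <- ratio(led, dataset = "synthetic")
  expect_equal(rr$r, rr$r_adj + rr$r_chg, tolerance = 1e-9)
  expect_true(all(rr$r >= 0))
})

test_that("envelope estimators behave as bounds", {
  ## single record: slope equals its ratio
  expect_equal(envelopeSlope(envelopeFit(0.25)), 0.25)
  rr <- ratio(genEnergyTable(n = 2000L, seed = 3L), dataset = "synthetic")
  fitMax <- envelopeFit(rr, "max-ratio")
  ## max-ratio covers every record and dominates any upper quantile
  expect_true(all(rr$r <= envelopeSlope(fitMax)))
  for (lev in c(0.9, 0.99, 0.999))
    expect_lte(envelopeSlope(envelopeFit(rr, "upper-quantile", lev)),
               envelopeSlope(fitMax))
  ## adding a record below the maximum leaves the max-ratio slope unchanged
  expect_equal(envelopeSlope(envelopeFit(c(rr$r, 0.01))),
               envelopeSlope(fitMax))
  expect_error(envelopeFit(numeric()), "no ratio records")
})

test_that("envelope recovery: the 0.40 truncation is found across seeds", {
  slopes <- vapply(1:20, function(s)
    envelopeSlope(envelopeFit(ratio(genEnergyTable(n = 1e4L, seed = s),
                                    dataset = "synthetic"))),
    numeric(1L))
  expect_true(all(slopes >= 0.38))
  expect_true(all(slopes <= 0.40))
})

test_that("cumulative fractions are a valid CDF evaluation matching the closed form", {
  led <- genEnergyTable(n = 1e5L, seed = 17L)
  rr <- ratio(led, dataset = "synthetic")
  th <- c(0.05, 0.10, 0.15, 0.25, 0.40)
  fr <- cumulativeFractions(rr, th)
  ## monotone, bounded, exact at the truncation
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(unname(fr[length(fr)]), 1)
  expect_equal(unname(cumulativeFractions(rr, min(rr$r) / 2)), 0)
  ## agrees with the analytic triangular CDF at n = 1e5
  expect_equal(unname(fr),
               LatticePartition:::ptriangular(th, 0, 0.1, 0.4),
               tolerance = 0.01)
  expect_error(cumulativeFractions(rr, c(0.4, 0.1)), "ascending")
})

test_that("component linear fits recover generator parameters", {
  ## collinear points with slope -0.2 fit exactly
  eInter <- -seq(100, 400, by = 50)
  col <- data.frame(structure_id = sprintf("S%d", seq_along(eInter)),
                    compound_id = "S", inter_model = "m", intra_model = "m",
                    E_inter = eInter, E_adjustment = -0.2 * eInter,
                    dE_change_global = 0, E_intra_global = -0.2 * eInter,
                    E_latt_global = eInter - 0.2 * eInter)
  fits <- intraLinearFit(col)
  ig <- fits[fits$component == "intra_global", ]
  expect_equal(ig$slope, -0.2, tolerance = 1e-12)
  expect_equal(ig$r_squared, 1, tolerance = 1e-12)
  ## symmetric ratio density with mean 0.15: recovered slope within 3 s.e.
  led <- genEnergyTable(n = 1e4L, seed = 23L, ratioMin = 0.05,
                        ratioMode = 0.15, ratioMax = 0.25)
  f2 <- intraLinearFit(led)
  slope <- f2$slope[f2$component == "intra_global"]
  se <- 3 * sd(ratio(led, "s")$r) / sqrt(nrow(led)) /
    sd(led$E_inter) * mean(abs(led$E_inter))
  expect_lt(abs(slope - (-0.15)), max(3 * se, 0.01))
  ## adjustment-dominated generator: adjustment slope dominates the change one
  f3 <- intraLinearFit(genEnergyTable(n = 5000L, seed = 31L))
  expect_gt(abs(f3$slope[f3$component == "adjustment"]),
            abs(f3$slope[f3$component == "change_global"]))
  expect_error(intraLinearFit(col[1:2, ]), "at least 3")
})

test_that("kink-site scores match the analytic growth-energetics argument", {
  ## r = 0.4, f = 0.5: net gain is 10% of |E_inter|
  expect_equal(as.numeric(kinkScore(-100, eIntraGlobal = 40, f = 0.5)), 10)
  ## boundary r = f: zero net gain
  expect_equal(as.numeric(kinkScore(-100, eIntraGlobal = 50, f = 0.5)), 0)
  ## r = 0.2 at |E_inter| = 200: +60 kJ/mol
  expect_equal(as.numeric(kinkScore(-200, eIntraGlobal = 40, f = 0.5)), 60)
  ## EnergyPartition method agrees, and r > f flags unfavorable
  p <- assemblePartition(-100, 55, 0)
  s <- kinkScore(p, f = 0.5)
  expect_equal(as.numeric(s), -5)
  expect_false(attr(s, "favorable"))
  expect_error(kinkScore(-100, eIntraGlobal = 10, f = 0), "'f'")
  expect_error(kinkScore(100, eIntraGlobal = 10), "negative")
})

test_that("the crystallizability report is deterministic, row-stable and flags high ratios", {
  beta <- workedExamples[workedExamples$form == "beta", ]
  led <- data.frame(structure_id = c(beta$structure_id, "RIGID01"),
                    compound_id = c(beta$compound_id, "RIGID"),
                    inter_model = "pbe-mbd", intra_model = "b2plypd",
                    E_inter = c(beta$E_inter, -150),
                    E_adjustment = c(beta$E_intra_global, 0),
                    dE_change_global = 0,
                    E_intra_global = c(beta$E_intra_global, 0),
                    E_latt_global = c(beta$E_latt_global, -150))
  rep1 <- crystallizabilityReport(led)
  rep2 <- crystallizabilityReport(led)
  expect_identical(rep1, rep2)
  expect_identical(rep1$structure_id, led$structure_id)
  ## the high-ratio form sits far up the reference distribution; the rigid
  ## molecule at its bottom
  expect_equal(round(rep1$r[1L], 2), 0.35)
  expect_gt(rep1$percentile[1L], 95)
  expect_lte(rep1$percentile[2L], 1)
  expect_equal(rep1$r[2L], 0)
  ## r = 0.35 < f = 0.5: kink incorporation still favorable, not high-ratio
  expect_true(rep1$kink_favorable[1L])
  expect_false(rep1$high_ratio[1L])
})
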