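test_that("gebv computes mu + sum of beta over both haplotypes", {
  g <- PhasedGenotypes(matrix(c(1L, 1L), 2, 1), matrix(c(1L, 0L), 2, 1))
  expect_equal(unname(gebv(g, TraitModel(c(1, 2)))), 4)

  allMinor <- PhasedGenotypes(matrix(0L, 3, 2), matrix(0L, 3, 2))
  expect_equal(unname(gebv(allMinor, TraitModel(c(1, -2, 3)))), c(0, 0))

  beta <- c(0.5, -1, 2)
  allMajor <- PhasedGenotypes(matrix(1L, 3, 2), matrix(1L, 3, 2))
  expect_equal(unname(gebv(allMajor, TraitModel(beta, mu = 7))),
               rep(7 + 2 * sum(beta), 2))

  expect_error(gebv(g, TraitModel(c(1, 2, 3))), "loci")
})

test_that("potentials match the per-locus extreme formulas and bound GEBVs", {
  mono <- PhasedGenotypes(matrix(1L, 2, 3), matrix(1L, 2, 3))
  tr <- TraitModel(c(1, 2))
  expect_equal(lowerPotential(mono, tr), 2 * 3)
  expect_equal(upperPotential(mono, tr), 2 * 3)

  # both alleles segregating at both loci, beta = (1, -1)
  seg <- PhasedGenotypes(matrix(c(1L, 0L, 0L, 1L), 2, 2),
                         matrix(c(0L, 1L, 1L, 0L), 2, 2))
  trpm <- TraitModel(c(1, -1))
  expect_equal(lowerPotential(seg, trpm), -2)
  expect_equal(upperPotential(seg, trpm), 2)

  for (seed in 1:5) {
    inst <- makeInstance(6, 15, 2, seed = seed)
    v <- gebv(inst$geno, inst$trait)
    lo <- lowerPotential(inst$geno, inst$trait)
    up <- upperPotential(inst$geno, inst$trait)
    expect_true(all(v - overallMean(inst$trait) >= lo - 1e-12))
    expect_true(all(v - overallMean(inst$trait) <= up + 1e-12))
  }
})

test_that("present value discounts per-generation bests", {
  expect_equal(presentValueOfGains(c(3, 1, 4), lambda = 0), 8)
  expect_equal(presentValueOfGains(c(1.1, 1.21), lambda = 0.1), 2)
  expect_equal(presentValueOfGains(10, lambda = 0.25), 8)
  expect_equal(presentValueOfGains(GainLedger(c(1.1, 1.21), 0.1)), 2)

  # strictly decreasing in lambda when any best is positive
  best <- c(-1, 2, 0.5)
  pvs <- vapply(c(0, 0.1, 0.5, 1), function(l)
    presentValueOfGains(best, l), numeric(1))
  expect_true(all(diff(pvs) < 0))

  expect_error(presentValueOfGains(numeric(0)), "empty")
  expect_error(presentValueOfGains(1, lambda = -0.1), "lambda")
})

test_that("identity block partition reproduces per-locus scores and map", {
  inst <- makeInstance(4, 12, 2, seed = 3)
  bp <- aggregateBlocks(inst$geno, inst$trait, inst$map, 12)
  expect_equal(bp@scores1,
               haplotypes(inst$geno, 1) * markerEffects(inst$trait),
               ignore_attr = TRUE)
  expect_equal(recombFreq(bp), recombFreq(inst$map))
  expect_equal(nBlocks(bp), 12L)
})

test_that("inter-block gap aggregates spanned intervals as 1 - prod(1 - r)", {
  # 3 loci, one chromosome, blocks {1,2} and {3}: the gap between the
  # block midpoints spans both intervals
  g <- PhasedGenotypes(matrix(1L, 3, 2), matrix(0L, 3, 2))
  tr <- TraitModel(c(1, 1, 1))
  map <- GeneticMap(c(0.1, 0.2), rep(1L, 3))
  bp <- aggregateBlocks(g, tr, map, 2)
  expect_equal(bp@blockStart, c(1L, 3L))
  expect_equal(recombFreq(bp), 1 - 0.9 * 0.8)
})

test_that("aggregation preserves GEBVs exactly and validates the partition", {
  for (seed in 1:4) {
    inst <- makeInstance(5, 30, 3, seed = seed)
    for (nb in c(3, 7, 15, 30)) {
      bp <- aggregateBlocks(inst$geno, inst$trait, inst$map, nb)
      expect_equal(gebv(bp), gebv(inst$geno, inst$trait))
      # blocked potentials are the blocked-representation analogue: they
      # nest inside the SNP-level bounds and coincide at identity blocks
      expect_gte(lowerPotential(bp),
                 lowerPotential(inst$geno, inst$trait) - 1e-9)
      expect_lte(upperPotential(bp),
                 upperPotential(inst$geno, inst$trait) + 1e-9)
      if (nb == 30) {
        expect_equal(lowerPotential(bp),
                     lowerPotential(inst$geno, inst$trait))
        expect_equal(upperPotential(bp),
                     upperPotential(inst$geno, inst$trait))
      }
      bnd <- which(diff(chromAssign(bp)) != 0L)
      expect_true(all(recombFreq(bp)[bnd] == 0.5))
    }
  }
  inst <- makeInstance(3, 10, 3, seed = 9)
  expect_error(aggregateBlocks(inst$geno, inst$trait, inst$map, 2),
               "chromosomes")
  expect_error(aggregateBlocks(inst$geno, inst$trait, inst$map, 11),
               "exceeds")
})
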