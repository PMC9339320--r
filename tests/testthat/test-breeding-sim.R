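test_that("program configuration validates its invariants", {
  cfg <- programConfig(N = 20, S = 4, T = 3, method = "cgs")
  expect_equal(cfg$progenyPerCross, 5L)
  expect_error(programConfig(N = 10, S = 3, T = 2), "divide")
  expect_error(programConfig(N = 10, S = 2, T = 0), "T")
  expect_error(programConfig(N = 10, S = 2, T = 2, nReplicates = 0),
               "nReplicates")
})

test_that("one generation produces N progeny split equally across crosses", {
  inst <- makeInstance(20, 30, 2, seed = 101)
  bp <- aggregateBlocks(inst$geno, inst$trait, inst$map, 10)
  cfg <- programConfig(N = 20, S = 4, T = 3, method = "cgs", K = 30)
  set.seed(1)
  step <- runGeneration(bp, cfg)
  expect_equal(nInd(step$pop), 20L)
  expect_equal(generationIndex(step$pop), 1L)
  expect_length(checkFeasibility(step$plan, 20, 4), 0)
  expect_named(step$metrics, c("generation", "mean_gebv",
                               "lower_potential", "upper_potential",
                               "best_gebv"))
})

test_that("a monomorphic founder population is a fixed point of the program", {
  g <- PhasedGenotypes(matrix(1L, 6, 10), matrix(1L, 6, 10))
  tr <- TraitModel(rnorm(6))
  map <- GeneticMap(rep(0.2, 5), rep(1L, 6))
  for (m in c("cgs", "pvlas")) {
    cfg <- programConfig(N = 10, S = 2, T = 3, method = m, K = 25,
                         nReplicates = 1, seed = 5)
    set.seed(5)
    tab <- runProgram(g, tr, map, cfg)
    expect_equal(tab$mean_gebv, rep(2 * sum(markerEffects(tr)), 3))
    expect_equal(tab$lower_potential, tab$upper_potential)
  }
})

test_that("potentials narrow monotonically as alleles are lost", {
  for (seed in 1:6) {
    inst <- makeInstance(12, 24, 2, seed = 110 + seed)
    m <- c("cgs", "las", "pvlas")[seed %% 3 + 1]
    cfg <- programConfig(N = 12, S = 3, T = 4, method = m, K = 40,
                         W = 2, seed = seed)
    set.seed(seed)
    tab <- runProgram(inst$geno, inst$trait, inst$map, cfg)
    founderLo <- lowerPotential(inst$geno, inst$trait)
    founderUp <- upperPotential(inst$geno, inst$trait)
    expect_true(all(diff(c(founderUp, tab$upper_potential)) <= 1e-9))
    expect_true(all(diff(c(founderLo, tab$lower_potential)) >= -1e-9))
    expect_true(all(tab$mean_gebv >= tab$lower_potential - 1e-9 &
                    tab$mean_gebv <= tab$upper_potential + 1e-9))
  }
})

test_that("the PV criterion reduces to the sum of bests at lambda 0", {
  inst <- makeInstance(8, 12, 1, seed = 121)
  cfg <- programConfig(N = 8, S = 2, T = 3, method = "cgs", K = 20,
                       evalLambda = 0)
  set.seed(2)
  tab <- runProgram(inst$geno, inst$trait, inst$map, cfg)
  expect_equal(tab$pv[1], sum(tab$best_gebv))
  expect_equal(nrow(tab), 3L)
})

test_that("CGS output ignores the look-ahead parameters", {
  inst <- makeInstance(10, 15, 1, seed = 131)
  mk <- function(W, K, gamma) programConfig(N = 10, S = 2, T = 2,
    method = "cgs", W = W, K = K, gamma = gamma, seed = 9)
  set.seed(9); t1 <- runProgram(inst$geno, inst$trait, inst$map,
                                mk(1, 10, 0.5))
  set.seed(9); t2 <- runProgram(inst$geno, inst$trait, inst$map,
                                mk(5, 400, 0.95))
  expect_identical(t1, t2)
})

test_that("replicated runs are reproducible and summarized correctly", {
  inst <- makeInstance(30, 20, 2, seed = 141)
  cfg <- programConfig(N = 10, S = 2, T = 2, method = "pvlas", W = 2,
                       K = 25, nReplicates = 3, seed = 77)
  r1 <- runReplicates(cfg, inst$geno, inst$trait, inst$map)
  r2 <- runReplicates(cfg, inst$geno, inst$trait, inst$map)
  expect_identical(r1$trajectories, r2$trajectories)
  expect_equal(nrow(r1$trajectories), 6L)
  expect_equal(r1$summary$meanPv,
               mean(r1$trajectories$pv[r1$trajectories$generation == 1]))

  cfg1 <- programConfig(N = 10, S = 2, T = 2, method = "cgs",
                        nReplicates = 1, seed = 3)
  rs <- runReplicates(cfg1, inst$geno, inst$trait, inst$map)
  expect_equal(rs$summary$meanTrajectory$mean_gebv,
               rs$trajectories$mean_gebv)
})

test_that("a sweep arm at the benchmark value differs by exactly zero", {
  inst <- makeInstance(24, 16, 2, seed = 151)
  cfg <- programConfig(N = 8, S = 2, T = 2, method = "pvlas", W = 3,
                       K = 20, nReplicates = 2, seed = 13)
  tab <- runSweep(cfg, "W", values = c(1, 2), inst$geno, inst$trait,
                  inst$map)
  expect_equal(tab$diff_mean_gebv[tab$value == 1], c(0, 0))
  expect_equal(nrow(tab), 4L)
  tabL <- runSweep(cfg, "lambda", values = 0, inst$geno, inst$trait,
                   inst$map)
  expect_equal(tabL$diff_mean_gebv, c(0, 0))
})
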