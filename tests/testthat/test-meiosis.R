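test_that("meiosis respects the no-recombination and homozygous limits", {
  set.seed(1)
  h1 <- c(1, 1, 0, 0); h2 <- c(0, 1, 1, 0)
  g <- sampleGametes(h1, h2, rep(0, 3), n = 200)
  expect_true(all(apply(g, 2, identical, h1) | apply(g, 2, identical, h2)))
  frac <- mean(apply(g, 2, identical, h1))
  expect_gt(frac, 0.35); expect_lt(frac, 0.65)

  same <- sampleGametes(h1, h1, c(0.1, 0.5, 0.3), n = 50)
  expect_true(all(same == h1))
})

test_that("gametes are mosaics of the parental haplotypes (no mutation)", {
  for (seed in 1:5) {
    set.seed(seed)
    h1 <- rbinom(8, 1, 0.5); h2 <- rbinom(8, 1, 0.5)
    r <- runif(7, 0, 0.5)
    g <- sampleGametes(h1, h2, r, n = 100)
    expect_true(all(g == h1 | sweep(g, 1, h2, "==")))
  }
})

test_that("enumeration oracle matches the two-locus closed form and sums to 1", {
  tab1 <- enumerateGameteDistribution(1, 0, numeric(0))
  expect_equal(tab1$prob[order(tab1$haplotype)], c(0.5, 0.5))

  tab <- enumerateGameteDistribution(c(1, 1), c(0, 0), 0.1)
  expect_equal(tab$prob[tab$haplotype == "1/1"], 0.45)
  expect_equal(tab$prob[tab$haplotype == "1/0"], 0.05)
  expect_equal(tab$prob[tab$haplotype == "0/1"], 0.05)
  expect_equal(tab$prob[tab$haplotype == "0/0"], 0.45)

  set.seed(4)
  tabr <- enumerateGameteDistribution(rbinom(6, 1, .5), rbinom(6, 1, .5),
                                      runif(5, 0, 0.5))
  expect_lt(abs(sum(tabr$prob) - 1), 1e-12)
  expect_error(enumerateGameteDistribution(rep(1, 20), rep(0, 20),
                                           runif(19, 0, .5)), "refused")
})

test_that("empirical gamete distribution matches enumeration", {
  set.seed(10)
  h1 <- c(1, 0, 1); h2 <- c(0, 1, 1); r <- c(0.15, 0.4)
  exact <- enumerateGameteDistribution(h1, h2, r)
  g <- sampleGametes(h1, h2, r, n = 20000)
  expect_lt(tvDistance(g, exact), 0.02)
})

test_that("adjacent loci assort independently at r = 0.5", {
  set.seed(2)
  g <- sampleGametes(c(0, 0), c(1, 1), 0.5, n = 50000)
  tab <- table(g[1, ], g[2, ])
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("makeProgeny produces gamete pairs with incremented generation", {
  inst <- makeInstance(4, 6, 1, seed = 5)
  set.seed(1)
  kids <- makeProgeny(inst$geno, c(1, 2), 30, inst$map)
  expect_s4_class(kids, "PhasedGenotypes")
  expect_equal(nInd(kids), 30L)
  expect_equal(generationIndex(kids), 1L)

  # homozygous shared locus is fixed in all progeny
  h1 <- haplotypes(inst$geno, 1); h2 <- haplotypes(inst$geno, 2)
  hom <- which(h1[, 1] == h2[, 1] & h1[, 2] == h2[, 2] & h1[, 1] == h1[, 2])
  if (length(hom)) {
    expect_true(all(haplotypes(kids, 1)[hom, ] == h1[hom, 1]))
    expect_true(all(haplotypes(kids, 2)[hom, ] == h1[hom, 1]))
  }

  # progeny GEBVs bounded by parental-haplotype potentials
  v <- gebv(kids, inst$trait)
  pool <- poolFromPlan(inst$geno, inst$trait, matrix(c(1L, 2L), 1))
  lo <- 2 * sum(apply(pool, 1, min)); up <- 2 * sum(apply(pool, 1, max))
  expect_true(all(v >= lo - 1e-12 & v <= up + 1e-12))
})

test_that("selfing a heterozygous locus segregates 1:2:1", {
  par <- PhasedGenotypes(matrix(1L, 1, 1), matrix(0L, 1, 1))
  map <- GeneticMap(numeric(0), 1L)
  set.seed(3)
  kids <- makeProgeny(par, c(1, 1), 8000, map)
  dose <- haplotypes(kids, 1)[1, ] + haplotypes(kids, 2)[1, ]
  frac <- tabulate(dose + 1L, 3) / 8000
  expect_equal(frac, c(0.25, 0.5, 0.25), tolerance = 0.07)
})

test_that("lookahead recombination follows the inflation formula", {
  r <- c(0, 0.1, 0.3, 0.5)
  expect_equal(lookaheadRecomb(r, tau = 1, S = 10), rep(0, 4))
  expect_equal(lookaheadRecomb(r, tau = 2, S = 10), rep(0, 4))
  expect_equal(lookaheadRecomb(0.1, tau = 3, S = 10), 9 * (1 - 0.9^3) / 10)
  expect_equal(lookaheadRecomb(0, tau = 7, S = 4), 0)
  # non-decreasing in tau, bounded by (S-1)/S
  vals <- sapply(3:12, function(tau) lookaheadRecomb(r, tau, S = 5))
  expect_true(all(diff(t(vals)) >= -1e-15))
  expect_true(all(vals <= 4 / 5))
  expect_error(lookaheadRecomb(r, tau = 0, S = 2), "tau")
})

test_that("descendant progeny of a homozygous selfed parent are invariant", {
  g <- PhasedGenotypes(matrix(c(1L, 0L, 1L), 3, 1),
                       matrix(c(1L, 0L, 1L), 3, 1))
  tr <- TraitModel(c(2, -1, 0.5), mu = 3)
  map <- GeneticMap(c(0.2, 0.2), rep(1L, 3))
  v <- unname(gebv(g, tr))
  for (tau in c(1, 2, 3, 6)) {
    s <- simulateDescendantProgeny(g, MatingPlan(c(1, 1), 1), tau,
                                   tr, map, K = 40)
    expect_equal(s, rep(v, 40))
  }
})

test_that("one cross without recombination yields the four haplotype sums", {
  set.seed(6)
  inst <- makeInstance(2, 5, 1, seed = 8)
  map0 <- GeneticMap(rep(0, 4), rep(1L, 5))
  s <- simulateDescendantProgeny(inst$geno, MatingPlan(c(1, 2), 2), 1,
                                 inst$trait, map0, K = 4000)
  h <- poolFromPlan(inst$geno, inst$trait, matrix(c(1L, 2L), 1))
  sums <- outer(colSums(h[, 1:2]), colSums(h[, 3:4]), "+")
  expect_true(all(vapply(s, function(x)
    any(abs(x - sums) < 1e-9), logical(1))))
  frac <- vapply(as.vector(sums), function(u) mean(abs(s - u) < 1e-9),
                 numeric(1))
  expect_equal(frac, rep(0.25, 4), tolerance = 0.12)
})

test_that("simulated descendant means match the exact chain expectation", {
  set.seed(12)
  inst <- makeInstance(6, 3, 1, seed = 13)
  pairs <- matrix(c(1L, 2L, 3L, 4L, 5L, 5L), 3, 2, byrow = TRUE)
  pool <- poolFromPlan(inst$geno, inst$trait, pairs)
  r <- recombFreq(inst$map)
  for (tau in c(1, 2, 3, 5)) {
    s <- simulateDescendantProgeny(inst$geno, MatingPlan(pairs, 6), tau,
                                   inst$trait, inst$map, K = 10000)
    exact <- dpDescendantMean(pool, r, 3L, tau)
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - exact), 3 * se + 1e-9)
  }
})
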