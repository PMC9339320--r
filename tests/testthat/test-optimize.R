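test_that("checkFeasibility reports the violated constraints", {
  plan <- MatingPlan(rbind(c(1, 2), c(3, 4)), 8)
  expect_length(checkFeasibility(plan, 8, 2), 0)
  expect_equal(checkFeasibility(plan, 8, 3), "(7)")

  N <- 4
  Y <- matrix(0L, N, N); Y[1, 2] <- 1L   # asymmetric
  x <- c(1L, 1L, 0L, 0L)
  expect_true("(8)" %in% checkFeasibility(list(x = x, Y = Y), N, 1))

  Y2 <- matrix(0L, N, N); Y2[1, 2] <- Y2[2, 1] <- 1L
  x2 <- c(1L, 1L, 1L, 0L)   # individual 3 selected but unmated
  expect_true("(6)" %in% checkFeasibility(list(x = x2, Y = Y2), N, 1))

  x3 <- c(1L, 2L, 0L, 0L)
  expect_true("(9)" %in% checkFeasibility(list(x = x3, Y = Y2), N, 1))

  expect_length(checkFeasibility(list(x = x, Y = Y2), N, 1), 0)
})

test_that("plan normalization exposes x and Y consistent with the pairs", {
  plan <- MatingPlan(rbind(c(2, 5), c(3, 3)), 6)
  x <- selectionVector(plan)
  Y <- matingMatrix(plan)
  expect_equal(which(x == 1L), c(2L, 3L, 5L))
  expect_equal(Y, t(Y))
  expect_equal(Y[3, 3], 1L)
  expect_length(checkFeasibility(plan, 6, 2), 0)
})

test_that("CGS selects the top 2S and mates them by a uniform matching", {
  v <- c(9, 8, 7, 6, 5, 4)
  set.seed(1)
  counts <- integer(3)
  for (i in 1:1000) {
    plan <- selectCGS(v, 2)
    p <- crossPairs(plan)
    expect_setequal(as.vector(p), 1:4)
    key <- paste(t(p[order(p[, 1]), ]), collapse = "")
    m <- match(key, c("1234", "1324", "1423"))
    counts[m] <- counts[m] + 1L
  }
  expect_true(all(abs(counts / 1000 - 1 / 3) < 0.05))

  set.seed(2)
  top <- sort(unique(as.vector(crossPairs(selectCGS(c(1, 5, 3, 9), 1)))))
  expect_equal(top, c(2L, 4L))
  expect_error(selectCGS(c(1, 2, 3), 2), "2S")
})

test_that("the warm start pairs consecutive GEBV ranks and is feasible", {
  v <- c(10, 9, 8, 7, 6, 5)
  plan <- initialFeasiblePlan(v, 2)
  expect_equal(crossPairs(plan), rbind(c(1L, 2L), c(3L, 4L)),
               ignore_attr = TRUE)
  expect_length(checkFeasibility(plan, 6, 2), 0)

  inst <- makeInstance(8, 10, 1, seed = 51)
  p2 <- initialFeasiblePlan(inst$geno, 3, trait = inst$trait)
  expect_length(checkFeasibility(p2, 8, 3), 0)

  # warm start never worse than the worst feasible plan
  obj <- ohvObjective(inst$geno, inst$trait)
  all <- exhaustiveSearch(function(p) -obj(p), N = 8, S = 2)
  worst <- -all$value
  expect_gte(obj(initialFeasiblePlan(inst$geno, 2, trait = inst$trait)),
             worst)
})

test_that("local search improves monotonically and finds small-instance optima", {
  inst <- makeInstance(4, 8, 1, seed = 61)
  obj <- ohvObjective(inst$geno, inst$trait)
  start <- initialFeasiblePlan(inst$geno, 1, trait = inst$trait)
  set.seed(3)
  res <- localSearch(obj, start, N = 4, S = 1)
  expect_true(all(diff(res$trace) > 0) || length(res$trace) == 1)
  expect_gte(res$value, obj(start))
  ex <- exhaustiveSearch(obj, N = 4, S = 1)
  expect_equal(res$value, ex$value)

  # a globally optimal start is returned unchanged
  set.seed(4)
  res2 <- localSearch(obj, ex$plan, N = 4, S = 1)
  expect_identical(crossPairs(res2$plan), crossPairs(ex$plan))
  expect_error(localSearch(obj, MatingPlan(c(1, 2), 4), N = 4, S = 2),
               "infeasible")
})

test_that("local search never returns below its start under common random numbers", {
  for (seed in 1:6) {
    inst <- makeInstance(8, 10, 1, seed = seed + 70)
    spec <- LookAheadSpec(W = 2, lambda = 0.1, K = 60)
    st <- pvlas:::scoreState(inst$geno, inst$trait, inst$map)
    crn <- 1000L + seed
    segs <- pvlas:::lookaheadSegments(st, 2, 1:2, 60, crn)
    obj <- pvlas:::frozenLookaheadObjective(st, 1.1^-(1:2), 0.8, segs)
    start <- initialFeasiblePlan(inst$geno, 2, trait = inst$trait)
    set.seed(seed)
    res <- localSearch(obj, start, N = 8, S = 2, crnSeed = crn)
    expect_gte(res$value, obj(start))
    expect_length(checkFeasibility(res$plan, 8, 2), 0)
  }
})

test_that("exhaustive search enumerates all self-allowed plans", {
  ex <- exhaustiveSearch(function(p) sum(crossPairs(p)), N = 2, S = 1)
  expect_equal(ex$nPlans, 3)
  expect_equal(crossPairs(ex$plan), rbind(c(2L, 2L)), ignore_attr = TRUE)

  # total parental GEBV, selfing using its parent twice: selfing the best
  # individual beats crossing it with a weaker one
  v <- c(5, 1)
  cg <- exhaustiveSearch(function(p) sum(v[crossPairs(p)]), N = 2, S = 1)
  expect_equal(crossPairs(cg$plan), rbind(c(1L, 1L)), ignore_attr = TRUE)
  expect_error(exhaustiveSearch(identity, N = 200, S = 5), "guard")
})

test_that("selectWithMethod dispatches and always emits feasible plans", {
  inst <- makeInstance(8, 12, 2, seed = 81)
  v <- gebv(inst$geno, inst$trait)
  set.seed(6)
  p1 <- selectWithMethod(inst$geno, inst$trait, inst$map, "cgs", S = 2)
  set.seed(6)
  p2 <- selectCGS(v, 2)
  expect_identical(crossPairs(p1), crossPairs(p2))

  for (m in c("cgs", "las", "pvlas")) {
    set.seed(7)
    p <- selectWithMethod(inst$geno, inst$trait, inst$map, m, S = 3,
                          spec = LookAheadSpec(W = 2, K = 50), horizon = 4)
    expect_length(checkFeasibility(p, 8, 3), 0)
  }
  expect_error(selectWithMethod(inst$geno, inst$trait, inst$map, "las",
                                S = 2, spec = LookAheadSpec(K = 10)),
               "horizon")
})

test_that("incremental candidate evaluation matches full plan evaluation", {
  inst <- makeInstance(9, 20, 2, seed = 91)
  bp <- aggregateBlocks(inst$geno, inst$trait, inst$map, 10)
  st <- pvlas:::scoreState(bp)
  S <- 3
  segs <- pvlas:::lookaheadSegments(st, S, 1:3, 80, 5555L)
  w <- 1.1^-(1:3)
  obj <- pvlas:::frozenLookaheadObjective(st, w, 0.8, segs)
  inc <- rbind(c(1L, 4L), c(2L, 2L), c(5L, 9L))
  for (s in 1:S) for (side in 1:2) {
    keep <- inc[s, 3 - side]
    cand <- setdiff(1:9, inc[s, side])
    okey <- paste(inc[-s, 1], inc[-s, 2])
    cand <- cand[!paste(pmin(keep, cand), pmax(keep, cand)) %in% okey]
    fast <- pvlas:::.cppEvalReplacements(st$s1, st$s2, inc, s - 1L,
                                         side - 1L, as.integer(cand),
                                         segs, w, 0.8, st$mu)
    slow <- vapply(cand, function(k) {
      p <- inc; p[s, ] <- c(min(keep, k), max(keep, k))
      obj(MatingPlan(p, 9))
    }, numeric(1))
    expect_equal(fast, slow)
  }
})
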