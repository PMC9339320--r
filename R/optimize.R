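#' Check a mating plan against the selection/mating constraints
#'
#' Validates the integer-programming constraints of the mate-selection
#' formulation: (6) only selected individuals are mated
#' (\eqn{N^{-1}\sum_j y_{ij} \le x_i \le \sum_j y_{ij}}), (7) exactly S
#' crosses are made, (8) Y is symmetric, (9) x and Y are binary. A plan
#' given as a pair list is first normalized to (x, Y); a list with
#' elements `x` and `Y` is checked as-is, which allows probing raw
#' matrices for violations.
#'
#' @param plan a [MatingPlan-class], or a list with binary vector `x` and
#'   matrix `Y`.
#' @param N population size.
#' @param S required number of crosses.
#' @return Character vector of violated constraint labels among
#'   `"(6)", "(7)", "(8)", "(9)"`; empty when feasible. Violations are
#'   data, not errors.
#' @export
checkFeasibility <- function(plan, N, S) {
  if (is(plan, "MatingPlan")) {
    p <- plan@pairs
    if (plan@nInd != N || any(p < 1L) || any(p > N)) return("(9)")
    bad <- character(0)
    if (nrow(p) != S) bad <- c(bad, "(7)")
    return(bad)
  }
  x <- plan$x; Y <- plan$Y
  bad <- character(0)
  if (!all(x %in% c(0, 1)) || !all(Y %in% c(0, 1))) bad <- c(bad, "(9)")
  if (!isTRUE(all.equal(Y, t(Y)))) bad <- c(bad, "(8)")
  nPairs <- sum(Y[upper.tri(Y, diag = TRUE)] != 0)
  if (nPairs != S) bad <- c(bad, "(7)")
  rs <- rowSums(Y)
  if (any(rs / length(x) > x + 1e-12) || any(x > rs + 1e-12))
    bad <- c(bad, "(6)")
  bad
}

#' Truncation selection with random mating (CGS)
#'
#' Selects the 2S individuals with the highest GEBVs (ties broken by
#' ascending index) and pairs them by a uniformly random perfect matching
#' into S crosses; no selfing.
#'
#' @param v numeric GEBV vector of length N.
#' @param S number of crosses.
#' @return A [MatingPlan-class].
#' @export
selectCGS <- function(v, S) {
  N <- length(v)
  if (N < 2L * S) argError("N = %d cannot supply 2S = %d parents", N, 2 * S)
  top <- order(-v, seq_len(N))[seq_len(2L * S)]
  shuffled <- top[sample.int(2L * S)]
  MatingPlan(matrix(shuffled, ncol = 2L, byrow = TRUE), nInd = N)
}

#' Deterministic feasible warm start
#'
#' Pairs the top-2S individuals by GEBV rank (1 with 2, 3 with 4, ...),
#' giving a feasible starting plan for the local search.
#'
#' @param v numeric GEBV vector, or a [PhasedGenotypes-class] /
#'   [BlockedPopulation-class] (with `trait` for phased genotypes).
#' @param S number of crosses.
#' @param trait a [TraitModel-class] when `v` is a phased population.
#' @return A [MatingPlan-class].
#' @export
initialFeasiblePlan <- function(v, S, trait = NULL) {
  if (is(v, "PhasedGenotypes")) v <- gebv(v, trait)
  else if (is(v, "BlockedPopulation")) v <- gebv(v)
  N <- length(v)
  if (N < 2L * S) argError("N = %d cannot supply 2S = %d parents", N, 2 * S)
  top <- order(-v, seq_len(N))[seq_len(2L * S)]
  MatingPlan(matrix(top, ncol = 2L, byrow = TRUE), nInd = N)
}

#' Pair-replacement local search over mating plans
#'
#' Iterative improvement heuristic: each pass visits every (cross,
#' parent-slot) of the incumbent in random order; for the visited slot it
#' evaluates all feasible neighbor plans that replace that parent with a
#' candidate k in 1..N (keeping the co-parent), and replaces the incumbent
#' with the best strictly improving neighbor. The search repeats until a
#' full pass yields no improvement (`maxPasses` is a safety cap).
#'
#' Stochastic objectives are evaluated under common random numbers: one
#' CRN seed is drawn at the start and every objective evaluation in the
#' search runs under it, which makes plan comparisons well-defined and
#' guarantees the returned objective is >= the start's.
#'
#' @param objective function taking a [MatingPlan-class] and returning a
#'   single finite number to maximize.
#' @param start a feasible [MatingPlan-class].
#' @param N population size.
#' @param S number of crosses.
#' @param maxPasses safety cap on the number of passes (default 40).
#' @param selfing allow neighbors with k equal to the kept parent.
#' @param crnSeed common-random-number seed; drawn from the current RNG
#'   stream when NULL.
#' @return List with `plan` (the locally optimal [MatingPlan-class]),
#'   `value` (its objective under the CRN seed), `trace` (strictly
#'   increasing incumbent objective values), and `passes`.
#' @export
localSearch <- function(objective, start, N, S, maxPasses = 40L,
                        selfing = TRUE, crnSeed = NULL) {
  if (!is(start, "MatingPlan")) argError("start must be a MatingPlan")
  if (length(checkFeasibility(start, N, S)))
    argError("start plan is infeasible")
  if (is.null(crnSeed)) crnSeed <- drawSeed()
  template <- MatingPlan(start@pairs, nInd = N)
  slotEval <- function(inc, s, side, candidates) {
    keep <- inc[s, 3L - side]
    vapply(candidates, function(k) {
      cand <- inc
      cand[s, ] <- c(min(keep, k), max(keep, k))
      template@pairs <- cand
      withSeed(crnSeed, objective(template))
    }, numeric(1))
  }
  startValue <- withSeed(crnSeed, objective(start))
  res <- localSearchCore(slotEval, start@pairs, startValue, N, S,
                         maxPasses, selfing)
  list(plan = MatingPlan(res$pairs, nInd = N), value = res$value,
       trace = res$trace, passes = res$passes)
}

# Shared pass logic of the pair-replacement heuristic. slotEval(inc, s,
# side, candidates) returns one objective value per candidate replacement
# parent for slot (cross s, position side) of the incumbent pair matrix.
# Both the generic closure path and the fast frozen-trajectory path run
# through this, with identical RNG consumption (one permutation per
# pass), so they produce identical searches.
localSearchCore <- function(slotEval, startPairs, startValue, N, S,
                            maxPasses, selfing) {
  inc <- startPairs
  best <- startValue
  trace <- best
  passes <- 0L
  repeat {
    passes <- passes + 1L
    improved <- FALSE
    slots <- cbind(rep(seq_len(S), 2L), rep(1:2, each = S))
    slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
    for (u in seq_len(nrow(slots))) {
      s <- slots[u, 1L]; side <- slots[u, 2L]
      keep <- inc[s, 3L - side]
      cur <- inc[s, side]
      okey <- paste(inc[-s, 1L], inc[-s, 2L])
      candidates <- seq_len(N)
      candidates <- candidates[candidates != cur]
      if (!selfing) candidates <- candidates[candidates != keep]
      nk <- paste(pmin(keep, candidates), pmax(keep, candidates))
      candidates <- candidates[!nk %in% okey]
      if (!length(candidates)) next
      vals <- slotEval(inc, s, side, candidates)
      w <- which.max(vals)
      if (vals[w] > best) {
        k <- candidates[w]
        inc[s, ] <- c(min(keep, k), max(keep, k))
        best <- vals[w]
        trace <- c(trace, best)
        improved <- TRUE
      }
    }
    if (!improved || passes >= maxPasses) break
  }
  list(pairs = inc, value = best, trace = trace, passes = passes)
}

#' Exhaustive search over all feasible mating plans
#'
#' Enumerates every set of S distinct unordered parent pairs (selfing
#' optionally allowed) and returns the plan maximizing the objective;
#' ties are broken lexicographically by the sorted pair list. Intended as
#' a ground-truth oracle for small instances.
#'
#' @inheritParams localSearch
#' @param selfing allow self-crosses (default TRUE).
#' @param maxPlans enumeration guard (default 1e6 candidate plans).
#' @return List with `plan`, `value`, and `nPlans` enumerated.
#' @export
exhaustiveSearch <- function(objective, N, S, selfing = TRUE,
                             maxPlans = 1e6) {
  pr <- which(upper.tri(diag(N), diag = selfing), arr.ind = TRUE)
  pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
  P <- nrow(pr)
  if (S > P) argError("S = %d exceeds the %d available pairs", S, P)
  nPlans <- choose(P, S)
  if (nPlans > maxPlans)
    argError("%.0f candidate plans exceed the enumeration guard", nPlans)
  combos <- utils::combn(P, S)
  bestVal <- -Inf; bestPlan <- NULL
  for (c in seq_len(ncol(combos))) {
    pairs <- pr[combos[, c], , drop = FALSE]
    plan <- MatingPlan(pairs, nInd = N)
    val <- objective(plan)
    if (val > bestVal) { bestVal <- val; bestPlan <- plan }
  }
  list(plan = bestPlan, value = bestVal, nPlans = nPlans)
}

#' Select a mating plan by a named method
#'
#' Dispatcher for the three selection strategies: `"cgs"` (truncation
#' selection with random mating), `"las"` (local search on the
#' terminal-horizon quantile objective), `"pvlas"` (local search on the
#' discounted sliding-window objective). LAS and PV-LAS start from
#' [initialFeasiblePlan()] and use common random numbers within the
#' search.
#'
#' @param x a [PhasedGenotypes-class] or [BlockedPopulation-class].
#' @param trait,map required for phased genotypes.
#' @param method one of `"cgs"`, `"las"`, `"pvlas"`.
#' @param S number of crosses.
#' @param spec a [LookAheadSpec-class] (ignored by CGS).
#' @param horizon remaining generations T - t (required for LAS).
#' @param maxPasses passed to [localSearch()].
#' @return A feasible [MatingPlan-class].
#' @export
selectWithMethod <- function(x, trait = NULL, map = NULL,
                             method = c("cgs", "las", "pvlas"), S,
                             spec = LookAheadSpec(), horizon = NULL,
                             maxPasses = 40L) {
  method <- match.arg(method)
  v <- if (is(x, "BlockedPopulation")) gebv(x) else gebv(x, trait)
  N <- length(v)
  if (method == "cgs") return(selectCGS(v, S))
  st <- scoreState(x, trait, map)
  if (method == "las") {
    if (is.null(horizon)) argError("las requires a horizon")
    taus <- as.integer(horizon)
    weights <- 1
  } else {
    taus <- seq_len(spec@W)
    # normalized to the first offset: the argmax is unchanged and a W = 1
    # window reduces bitwise to horizon-1 LAS under the same seed
    weights <- (1 + spec@lambda)^(-(taus - 1L))
  }
  crnSeed <- drawSeed()
  segs <- lookaheadSegments(st, S, taus, spec@K, crnSeed)
  obj <- frozenLookaheadObjective(st, weights, spec@gamma, segs)
  start <- initialFeasiblePlan(v, S)
  slotEval <- function(inc, s, side, candidates)
    .cppEvalReplacements(st$s1, st$s2, inc, s - 1L, side - 1L,
                         as.integer(candidates), segs, weights,
                         spec@gamma, st$mu)
  res <- localSearchCore(slotEval, start@pairs, obj(start), N, S,
                         maxPasses, selfing = TRUE)
  MatingPlan(res$pairs, nInd = N)
}

# One frozen draw of the look-ahead recombination trajectories (they
# depend only on r, S and tau, not on which individuals are crossed), so
# the same draw serves every candidate plan in a search: common random
# numbers by construction.
lookaheadSegments <- function(st, S, taus, K, crnSeed) {
  withSeed(crnSeed, lapply(taus, function(tau)
    .cppSampleSegments(st$r, as.integer(S), as.integer(tau),
                       as.integer(K))))
}

# Deterministic objective closure over a frozen trajectory draw: a plan
# evaluation is a segment-sum over its pool columns followed by the
# gamma-quantile at each offset and the weighted (discounted) total.
frozenLookaheadObjective <- function(st, weights, gamma, segs) {
  function(plan) {
    pool <- crossPool(st$s1, st$s2, plan@pairs)
    psi <- vapply(segs, function(sg)
      gammaQuantile(
        st$mu + .cppSegmentScores(pool, sg$gamStart, sg$segEnd, sg$segCol),
        gamma), numeric(1))
    sum(psi * weights)
  }
}
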