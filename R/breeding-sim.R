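#' Breeding-program configuration
#'
#' Bundles the parameters of a multi-generation genomic-selection
#' program. Defaults follow the published study conditions: N = 200
#' individuals per generation, S = 10 crosses (20 progeny each), T = 10
#' generations, discount rate lambda = 0.1, quantile gamma = 0.8, window
#' W = 3 and K = 500 simulated progeny.
#'
#' @param N population size per generation; must be divisible by S.
#' @param S crosses per generation.
#' @param T total generations to simulate.
#' @param method selection strategy: `"cgs"`, `"las"` or `"pvlas"`.
#' @param W look-ahead window (PV-LAS).
#' @param lambda discount rate of the PV-LAS objective.
#' @param gamma quantile parameter.
#' @param K Monte-Carlo progeny per objective evaluation.
#' @param nReplicates independent simulation replicates.
#' @param seed master seed; all replicate and search seeds derive from it.
#' @param evalLambda discount rate of the PV-of-GEBV evaluation criterion
#'   (defaults to `lambda`).
#' @param nBlocks optional SNP-to-block aggregation before simulation;
#'   NULL keeps one block per locus.
#' @param maxPasses local-search safety cap on passes.
#' @return A validated list of class `"ProgramConfig"`.
#' @export
programConfig <- function(N = 200L, S = 10L, T = 10L,
                          method = c("cgs", "las", "pvlas"),
                          W = 3L, lambda = 0.1, gamma = 0.8, K = 500L,
                          nReplicates = 1L, seed = 1L,
                          evalLambda = lambda, nBlocks = NULL,
                          maxPasses = 40L) {
  method <- match.arg(method)
  N <- as.integer(N); S <- as.integer(S); T <- as.integer(T)
  if (T < 1L) argError("T must be >= 1")
  if (S < 1L || N %% S != 0L) argError("S must divide N")
  if (nReplicates < 1L) argError("nReplicates must be >= 1")
  cfg <- list(N = N, S = S, T = T, method = method,
              spec = LookAheadSpec(W = W, lambda = lambda, gamma = gamma,
                                   K = K),
              nReplicates = as.integer(nReplicates),
              seed = as.integer(seed), evalLambda = evalLambda,
              nBlocks = if (is.null(nBlocks)) NULL else as.integer(nBlocks),
              maxPasses = as.integer(maxPasses),
              progenyPerCross = N %/% S)
  class(cfg) <- "ProgramConfig"
  cfg
}

metricsRow <- function(pop) {
  v <- gebv(pop)
  data.frame(generation = pop@generation,
             mean_gebv = mean(v),
             lower_potential = lowerPotential(pop),
             upper_potential = upperPotential(pop),
             best_gebv = max(v))
}

#' Advance a breeding program by one generation
#'
#' One selection + reproduction cycle: a mating plan is chosen with the
#' configured method (LAS uses the shrinking horizon T - t, PV-LAS always
#' looks W generations ahead), then each cross produces N/S progeny by
#' single-meiosis gametes from its two parents. Metrics are computed on
#' the new population.
#'
#' @param pop a [BlockedPopulation-class] (current generation t < T).
#' @param config a [programConfig()] list.
#' @return List with `pop` (next generation), `plan` (the
#'   [MatingPlan-class] used) and `metrics` (one-row data.frame with mean
#'   GEBV, lower/upper potential and best GEBV of the new population).
#' @export
runGeneration <- function(pop, config) {
  stopifnot(is(pop, "BlockedPopulation"), inherits(config, "ProgramConfig"))
  t <- pop@generation
  if (t >= config$T) argError("population is already at the final generation")
  plan <- selectWithMethod(pop, method = config$method, S = config$S,
                           spec = config$spec,
                           horizon = max(1L, config$T - t),
                           maxPasses = config$maxPasses)
  npc <- config$progenyPerCross
  kids <- lapply(seq_len(config$S), function(s)
    makeProgeny(pop, plan@pairs[s, ], npc))
  s1 <- do.call(cbind, lapply(kids, function(k) k@scores1))
  s2 <- do.call(cbind, lapply(kids, function(k) k@scores2))
  ids <- sprintf("g%d_%d", t + 1L, seq_len(ncol(s1)))
  colnames(s1) <- colnames(s2) <- ids
  nxt <- new("BlockedPopulation", scores1 = s1, scores2 = s2,
             blockChrom = pop@blockChrom, blockStart = pop@blockStart,
             blockEnd = pop@blockEnd, blockRecomb = pop@blockRecomb,
             mu = pop@mu, generation = t + 1L)
  list(pop = nxt, plan = plan, metrics = metricsRow(nxt))
}

#' Run a breeding program for T generations
#'
#' Initialization, then T selection/reproduction cycles. The founder
#' population is block-aggregated first (identity blocks when
#' `config$nBlocks` is NULL). The PV-of-GEBV criterion is computed from
#' the per-generation best GEBVs with the evaluation discount rate.
#'
#' @param founders a [PhasedGenotypes-class] founder panel of size
#'   `config$N` (or a ready [BlockedPopulation-class]).
#' @param trait,map required when `founders` is a PhasedGenotypes.
#' @param config a [programConfig()] list.
#' @param verbose emit per-generation progress messages to stderr.
#' @return data.frame with one row per generation: `generation`,
#'   `mean_gebv`, `lower_potential`, `upper_potential`, `best_gebv`, and
#'   the program-level `pv` repeated on every row.
#' @export
runProgram <- function(founders, trait = NULL, map = NULL, config,
                       verbose = FALSE) {
  pop <- if (is(founders, "BlockedPopulation")) founders else
    aggregateBlocks(founders, trait, map,
                    config$nBlocks %||% nLoci(founders))
  rows <- vector("list", config$T)
  for (g in seq_len(config$T)) {
    step <- runGeneration(pop, config)
    pop <- step$pop
    rows[[g]] <- step$metrics
    if (verbose)
      message(sprintf("generation %d/%d: mean GEBV %.4f", g, config$T,
                      step$metrics$mean_gebv))
  }
  out <- do.call(rbind, rows)
  out$pv <- presentValueOfGains(out$best_gebv, config$evalLambda)
  out
}

#' Run replicated breeding programs
#'
#' Per replicate, a fresh founder population is drawn from the founder
#' pool (without replacement when the pool holds at least N individuals,
#' with replacement otherwise) and a full program is run. Replicate seeds
#' are derived deterministically from the master seed, so identical
#' (config, seed) inputs give bit-identical outputs.
#'
#' @param config a [programConfig()] list (`nReplicates`, `seed` used).
#' @param founderPool a [PhasedGenotypes-class] pool to sample founders
#'   from, or a function(N) returning a PhasedGenotypes.
#' @param trait,map the trait model and genetic map.
#' @param verbose progress messages.
#' @return List with `trajectories` (stacked per-replicate data.frame
#'   with columns `replicate, generation, method, mean_gebv,
#'   lower_potential, upper_potential, best_gebv, pv`) and `summary`
#'   (per-generation means plus the empirical CDF of the replicate PVs).
#' @export
runReplicates <- function(config, founderPool, trait, map,
                          verbose = FALSE) {
  repSeeds <- withSeed(config$seed,
                       sample.int(.Machine$integer.max - 1L,
                                  config$nReplicates))
  res <- vector("list", config$nReplicates)
  for (rep in seq_len(config$nReplicates)) {
    res[[rep]] <- withSeed(repSeeds[rep], {
      founders <- sampleFounders(founderPool, config$N)
      tab <- runProgram(founders, trait, map, config)
      cbind(replicate = rep, tab[, "generation", drop = FALSE],
            method = config$method,
            tab[, c("mean_gebv", "lower_potential", "upper_potential",
                    "best_gebv", "pv")])
    })
    if (verbose)
      message(sprintf("replicate %d/%d done (PV %.4f)", rep,
                      config$nReplicates, res[[rep]]$pv[1L]))
  }
  traj <- do.call(rbind, res)
  rownames(traj) <- NULL
  meanTraj <- aggregate(
    traj[, c("mean_gebv", "lower_potential", "upper_potential",
             "best_gebv")],
    by = list(generation = traj$generation), FUN = mean)
  meanTraj <- cbind(method = config$method, meanTraj)
  pv <- sort(traj$pv[traj$generation == 1L])
  ecdfTab <- data.frame(method = config$method, pv = pv,
                        prob = seq_along(pv) / length(pv))
  list(trajectories = traj,
       summary = list(meanTrajectory = meanTraj, pvEcdf = ecdfTab,
                      meanPv = mean(pv)))
}

sampleFounders <- function(pool, N) {
  if (is.function(pool)) return(pool(N))
  stopifnot(is(pool, "PhasedGenotypes"))
  np <- nInd(pool)
  idx <- sample.int(np, N, replace = np < N)
  PhasedGenotypes(pool@hap1[, idx, drop = FALSE],
                  pool@hap2[, idx, drop = FALSE],
                  ids = paste0("f", seq_len(N)), generation = 0L)
}

#' Sensitivity sweep over W or lambda
#'
#' Reruns a PV-LAS program over a set of parameter values and reports,
#' per value and generation, the mean difference in GEBV from the
#' benchmark arm (W = 1 for the window sweep, lambda = 0 for the discount
#' sweep, the published benchmark choices). All arms share the same
#' replicate seeds, so founders are common across arms and a value equal
#' to the benchmark gives exactly zero differences.
#'
#' @param config a [programConfig()] list (method is forced to
#'   `"pvlas"`).
#' @param parameter `"W"` or `"lambda"`.
#' @param values numeric vector of parameter values to test.
#' @param founderPool,trait,map as in [runReplicates()].
#' @param verbose progress messages.
#' @return data.frame with columns `parameter, value, generation,
#'   mean_gebv, benchmark_mean_gebv, diff_mean_gebv`.
#' @export
runSweep <- function(config, parameter = c("W", "lambda"), values,
                     founderPool, trait, map, verbose = FALSE) {
  parameter <- match.arg(parameter)
  if (!length(values)) argError("values must be nonempty")
  config$method <- "pvlas"
  benchmark <- if (parameter == "W") 1L else 0
  armConfig <- function(val) {
    sp <- config$spec
    if (parameter == "W")
      cfg <- programConfig(config$N, config$S, config$T, "pvlas",
        W = val, lambda = sp@lambda, gamma = sp@gamma, K = sp@K,
        nReplicates = config$nReplicates, seed = config$seed,
        evalLambda = config$evalLambda, nBlocks = config$nBlocks,
        maxPasses = config$maxPasses)
    else
      cfg <- programConfig(config$N, config$S, config$T, "pvlas",
        W = sp@W, lambda = val, gamma = sp@gamma, K = sp@K,
        nReplicates = config$nReplicates, seed = config$seed,
        evalLambda = config$evalLambda, nBlocks = config$nBlocks,
        maxPasses = config$maxPasses)
    cfg
  }
  runArm <- function(val) {
    if (verbose) message(sprintf("sweep arm %s = %g", parameter, val))
    r <- runReplicates(armConfig(val), founderPool, trait, map)
    r$summary$meanTrajectory
  }
  base <- runArm(benchmark)
  out <- lapply(values, function(val) {
    arm <- runArm(val)
    data.frame(parameter = parameter, value = val,
               generation = arm$generation,
               mean_gebv = arm$mean_gebv,
               benchmark_mean_gebv = base$mean_gebv,
               diff_mean_gebv = arm$mean_gebv - base$mean_gebv)
  })
  do.call(rbind, out)
}
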