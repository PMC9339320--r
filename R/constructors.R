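#' Construct a PhasedGenotypes object
#'
#' @param hap1,hap2 L x N matrices of 0/1 alleles (one column per
#'   individual, one row per locus). Numeric input is coerced to integer.
#' @param ids optional character vector of N unique individual ids;
#'   defaults to existing column names or `ind1..indN`.
#' @param generation non-negative integer generation index (founders = 0).
#'
#' @return A [PhasedGenotypes-class] object.
#' @examples
#' g <- PhasedGenotypes(matrix(c(1L, 1L), 2, 1), matrix(c(1L, 0L), 2, 1))
#' gebv(g, TraitModel(c(1, 2)))
#' @export
PhasedGenotypes <- function(hap1, hap2, ids = NULL, generation = 0L) {
  hap1 <- as.matrix(hap1); hap2 <- as.matrix(hap2)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  if (is.null(ids)) ids <- colnames(hap1)
  if (is.null(ids)) ids <- paste0("ind", seq_len(ncol(hap1)))
  colnames(hap1) <- ids; colnames(hap2) <- ids
  new("PhasedGenotypes", hap1 = hap1, hap2 = hap2,
      generation = as.integer(generation))
}

#' Construct a TraitModel
#'
#' @param beta numeric vector of additive per-locus allele effects.
#' @param mu overall mean (default 0).
#' @return A [TraitModel-class] object.
#' @export
TraitModel <- function(beta, mu = 0) {
  new("TraitModel", beta = as.numeric(beta), mu = as.numeric(mu))
}

#' Construct a GeneticMap
#'
#' @param recomb numeric vector of length L - 1 of recombination
#'   frequencies in \[0, 0.5\]; entries at chromosome boundaries must be
#'   0.5 (they are forced to 0.5 when `enforceBoundaries = TRUE`).
#' @param chrom integer chromosome assignment per locus (default: one
#'   chromosome).
#' @param enforceBoundaries set boundary intervals to 0.5 rather than
#'   requiring the caller to (default TRUE).
#' @return A [GeneticMap-class] object.
#' @export
GeneticMap <- function(recomb, chrom = NULL, enforceBoundaries = TRUE) {
  recomb <- as.numeric(recomb)
  L <- length(recomb) + 1L
  if (is.null(chrom)) chrom <- rep(1L, L)
  chrom <- as.integer(chrom)
  if (enforceBoundaries && L > 1L) {
    bnd <- which(diff(chrom) != 0L)
    recomb[bnd] <- 0.5
  }
  new("GeneticMap", recomb = recomb, chrom = chrom)
}

#' Construct a LookAheadSpec
#'
#' Defaults follow the published study conditions: a W = 3 generation
#' window, discount rate lambda = 0.1, quantile gamma = 0.8 and K = 500
#' simulated progeny per offset.
#'
#' @param W window length in generations.
#' @param lambda per-generation discount rate (>= 0).
#' @param gamma quantile parameter in (0, 1).
#' @param K Monte-Carlo sample count.
#' @return A [LookAheadSpec-class] object.
#' @export
LookAheadSpec <- function(W = 3L, lambda = 0.1, gamma = 0.8, K = 500L) {
  new("LookAheadSpec", W = as.integer(W), lambda = as.numeric(lambda),
      gamma = as.numeric(gamma), K = as.integer(K))
}

#' Construct a MatingPlan from parent pairs
#'
#' @param pairs S x 2 matrix (or length-2 vector for S = 1) of parent
#'   indices; rows are unordered crosses, selfing (i, i) allowed.
#' @param nInd population size N the indices refer to.
#' @return A [MatingPlan-class] object.
#' @export
MatingPlan <- function(pairs, nInd) {
  if (is.null(dim(pairs))) pairs <- matrix(pairs, ncol = 2L, byrow = TRUE)
  pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]),
                 pmax(pairs[, 1L], pairs[, 2L]))
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- list(NULL, c("parent1", "parent2"))
  new("MatingPlan", pairs = pairs, nInd = as.integer(nInd))
}

#' Construct a GainLedger
#'
#' @param perGenerationBest numeric vector; max individual GEBV attained in
#'   each completed generation, in trait units.
#' @param lambda per-generation discount rate (>= 0).
#' @return A [GainLedger-class] object.
#' @export
GainLedger <- function(perGenerationBest, lambda = 0.1) {
  new("GainLedger", perGenerationBest = as.numeric(perGenerationBest),
      lambda = as.numeric(lambda))
}

## ---- accessors ----

#' Accessors for pvlas classes
#'
#' Small read-only accessors: population size `nInd()`, locus count
#' `nLoci()`, ids `indIds()`, generation index `generationIndex()`, trait
#' effects `markerEffects()` and `overallMean()`, map slots `recombFreq()`,
#' `chromAssign()`, `nChrom()`, block count `nBlocks()`, and mating-plan
#' views `crossPairs()`, `nCrosses()`, `selectionVector()`,
#' `matingMatrix()`.
#'
#' @param x a pvlas S4 object.
#' @name accessors
#' @aliases nInd nLoci indIds generationIndex markerEffects overallMean
#'   recombFreq chromAssign nChrom nBlocks crossPairs nCrosses
NULL

#' @rdname accessors
setMethod("nInd", "PhasedGenotypes", function(x) ncol(x@hap1))
#' @rdname accessors
setMethod("nInd", "BlockedPopulation", function(x) ncol(x@scores1))
#' @rdname accessors
setMethod("nLoci", "PhasedGenotypes", function(x) nrow(x@hap1))
#' @rdname accessors
setMethod("nLoci", "TraitModel", function(x) length(x@beta))
#' @rdname accessors
setMethod("nLoci", "GeneticMap", function(x) length(x@chrom))
#' @rdname accessors
setMethod("indIds", "PhasedGenotypes", function(x) colnames(x@hap1))
#' @rdname accessors
setMethod("indIds", "BlockedPopulation", function(x) colnames(x@scores1))
#' @rdname accessors
setMethod("generationIndex", "PhasedGenotypes", function(x) x@generation)
#' @rdname accessors
setMethod("generationIndex", "BlockedPopulation", function(x) x@generation)
#' @rdname accessors
setMethod("markerEffects", "TraitModel", function(x) x@beta)
#' @rdname accessors
setMethod("overallMean", "TraitModel", function(x) x@mu)
#' @rdname accessors
setMethod("overallMean", "BlockedPopulation", function(x) x@mu)
#' @rdname accessors
setMethod("recombFreq", "GeneticMap", function(x) x@recomb)
#' @rdname accessors
setMethod("recombFreq", "BlockedPopulation", function(x) x@blockRecomb)
#' @rdname accessors
setMethod("chromAssign", "GeneticMap", function(x) x@chrom)
#' @rdname accessors
setMethod("chromAssign", "BlockedPopulation", function(x) x@blockChrom)
#' @rdname accessors
setMethod("nChrom", "GeneticMap", function(x) length(unique(x@chrom)))
#' @rdname accessors
setMethod("nBlocks", "BlockedPopulation", function(x) nrow(x@scores1))
#' @rdname accessors
setMethod("crossPairs", "MatingPlan", function(x) x@pairs)
#' @rdname accessors
setMethod("nCrosses", "MatingPlan", function(x) nrow(x@pairs))

#' Haplotype matrix of a population
#'
#' @param x a [PhasedGenotypes-class] object.
#' @param m haplotype index, 1 or 2.
#' @return integer L x N allele matrix.
#' @export
haplotypes <- function(x, m = 1L) {
  stopifnot(is(x, "PhasedGenotypes"), m %in% c(1L, 2L))
  if (m == 1L) x@hap1 else x@hap2
}

#' Selection vector of a mating plan
#'
#' Binary length-N vector with x_i = 1 iff individual i appears in some
#' cross.
#'
#' @param plan a [MatingPlan-class] object.
#' @return integer vector of length N.
#' @export
selectionVector <- function(plan) {
  x <- integer(plan@nInd)
  x[unique(as.vector(plan@pairs))] <- 1L
  x
}

#' Symmetric mating matrix of a mating plan
#'
#' Binary N x N matrix with y_ij = y_ji = 1 for each cross (i, j);
#' selfing sets the diagonal entry.
#'
#' @param plan a [MatingPlan-class] object.
#' @return integer N x N matrix.
#' @export
matingMatrix <- function(plan) {
  N <- plan@nInd
  Y <- matrix(0L, N, N)
  for (s in seq_len(nrow(plan@pairs))) {
    i <- plan@pairs[s, 1L]; j <- plan@pairs[s, 2L]
    Y[i, j] <- 1L; Y[j, i] <- 1L
  }
  Y
}

## ---- show methods ----

setMethod("show", "PhasedGenotypes", function(object) {
  cat(sprintf(
    "PhasedGenotypes: %d individuals x %d loci (generation %d)\n",
    nInd(object), nLoci(object), object@generation))
})

setMethod("show", "TraitModel", function(object) {
  cat(sprintf(
    "TraitModel: %d loci, %d nonzero effects, mu = %g\n",
    length(object@beta), sum(object@beta != 0), object@mu))
})

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf(
    "GeneticMap: %d loci on %d chromosome(s), mean r = %.4g\n",
    nLoci(object), nChrom(object),
    if (length(object@recomb)) mean(object@recomb) else 0))
})

setMethod("show", "BlockedPopulation", function(object) {
  cat(sprintf(
    "BlockedPopulation: %d individuals x %d blocks (generation %d)\n",
    nInd(object), nBlocks(object), object@generation))
})

setMethod("show", "MatingPlan", function(object) {
  p <- object@pairs
  lab <- paste0(p[, 1L], ifelse(p[, 1L] == p[, 2L], " (self)",
                                paste0(" x ", p[, 2L])))
  cat(sprintf("MatingPlan: %d crosses over N = %d\n", nrow(p), object@nInd))
  cat(" ", paste(lab, collapse = ", "), "\n")
})

setMethod("show", "LookAheadSpec", function(object) {
  cat(sprintf("LookAheadSpec: W = %d, lambda = %g, gamma = %g, K = %d\n",
              object@W, object@lambda, object@gamma, object@K))
})

setMethod("show", "ObjectiveValue", function(object) {
  if (!is.na(object@zeta))
    cat(sprintf("ObjectiveValue: zeta = %.6g (lambda = %g)\n",
                object@zeta, object@lambda))
  else
    cat(sprintf("ObjectiveValue: phi = %.6g\n", object@phi))
  cat("  psi:", paste(sprintf("%.6g", object@psi), collapse = ", "), "\n")
})

setMethod("show", "GainLedger", function(object) {
  cat(sprintf("GainLedger: %d generation(s), lambda = %g, PV = %.6g\n",
              length(object@perGenerationBest), object@lambda,
              presentValueOfGains(object)))
})
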