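#' @useDynLib pvlas, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' Phased genotypes of a diploid population
#'
#' Binary phased allele state for N diploid individuals at L ordered
#' biallelic loci. Allele code 1 is the major (favorable-orientation)
#' allele, 0 the minor allele, following the usual additive-marker coding.
#' The two haplotypes are stored as separate L x N integer matrices so that
#' meiosis kernels can work on plain columns.
#'
#' @slot hap1,hap2 integer L x N matrices with entries in \{0, 1\}; column
#'   names are the individual identifiers.
#' @slot generation non-negative integer; founders are generation 0.
#'
#' @seealso [PhasedGenotypes()] for the constructor, [gebv()],
#'   [makeProgeny()], [aggregateBlocks()]
#' @exportClass PhasedGenotypes
setClass("PhasedGenotypes",
  representation(hap1 = "matrix", hap2 = "matrix", generation = "integer"))

setValidity("PhasedGenotypes", function(object) {
  h1 <- object@hap1; h2 <- object@hap2
  if (!identical(dim(h1), dim(h2)))
    return("hap1 and hap2 must have identical dimensions")
  if (nrow(h1) < 1L || ncol(h1) < 1L)
    return("need at least one locus and one individual")
  if (!all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L)))
    return("alleles must be 0 (minor) or 1 (major)")
  ids <- colnames(h1)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    return("individual ids must be unique non-empty column names")
  if (length(object@generation) != 1L || is.na(object@generation) ||
      object@generation < 0L)
    return("generation must be a single non-negative integer")
  TRUE
})

#' Additive trait model
#'
#' Per-marker additive allele effects plus an overall mean. An individual's
#' genomic estimated breeding value (GEBV) is
#' \eqn{v_i = \mu + \sum_l \beta_l (G_{l,1,i} + G_{l,2,i})}.
#'
#' @slot beta numeric vector of length L; additive effect of one copy of
#'   the major allele, in trait units.
#' @slot mu numeric scalar; overall mean, in trait units.
#'
#' @seealso [TraitModel()], [gebv()]
#' @exportClass TraitModel
setClass("TraitModel", representation(beta = "numeric", mu = "numeric"))

setValidity("TraitModel", function(object) {
  if (length(object@beta) < 1L || !all(is.finite(object@beta)))
    return("beta must be a non-empty finite numeric vector")
  if (length(object@mu) != 1L || !is.finite(object@mu))
    return("mu must be a single finite number")
  TRUE
})

#' Genetic map as per-interval recombination frequencies
#'
#' Recombination frequency \eqn{r_l} between adjacent loci l and l+1, plus
#' the chromosome assignment of each locus. Intervals that cross a
#' chromosome boundary carry r = 0.5 (independent assortment).
#'
#' @slot recomb numeric vector of length L - 1, values in \[0, 0.5\].
#' @slot chrom integer vector of length L, non-decreasing.
#'
#' @seealso [GeneticMap()], [sampleGamete()], [readMapTsv()]
#' @exportClass GeneticMap
setClass("GeneticMap", representation(recomb = "numeric", chrom = "integer"))

setValidity("GeneticMap", function(object) {
  r <- object@recomb; ch <- object@chrom
  if (length(ch) < 1L) return("chrom must assign at least one locus")
  if (length(r) != length(ch) - 1L)
    return("recomb must have length(chrom) - 1 entries")
  if (length(r) && (any(!is.finite(r)) || any(r < 0) || any(r > 0.5)))
    return("recombination frequencies must lie in [0, 0.5]")
  if (is.unsorted(ch)) return("chrom must be non-decreasing")
  bnd <- which(diff(ch) != 0L)
  if (length(bnd) && any(r[bnd] != 0.5))
    return("chromosome-boundary intervals must have r = 0.5")
  TRUE
})

#' Block-aggregated population
#'
#' Population state after SNP-to-block aggregation: each haplotype is
#' reduced to B per-block scores (the sum of beta * allele over the block's
#' member loci), inherited atomically with inter-block recombination
#' frequencies. GEBVs are preserved exactly:
#' \eqn{\mu + \sum_b (s_{b,1,i} + s_{b,2,i}) = v_i}.
#'
#' @slot scores1,scores2 numeric B x N matrices of per-block haplotype
#'   scores; column names are the individual ids.
#' @slot blockChrom integer vector of length B.
#' @slot blockStart,blockEnd integer vectors of length B; 1-based locus
#'   ranges of each block in the original marker order.
#' @slot blockRecomb numeric vector of length B - 1 in \[0, 0.5\]; 0.5 at
#'   chromosome boundaries.
#' @slot mu numeric scalar carried over from the trait model.
#' @slot generation non-negative integer.
#'
#' @seealso [aggregateBlocks()]
#' @exportClass BlockedPopulation
setClass("BlockedPopulation",
  representation(scores1 = "matrix", scores2 = "matrix",
    blockChrom = "integer", blockStart = "integer", blockEnd = "integer",
    blockRecomb = "numeric", mu = "numeric", generation = "integer"))

setValidity("BlockedPopulation", function(object) {
  s1 <- object@scores1; s2 <- object@scores2
  if (!identical(dim(s1), dim(s2)))
    return("scores1 and scores2 must have identical dimensions")
  B <- nrow(s1)
  if (B < 1L || ncol(s1) < 1L) return("need at least one block and individual")
  if (length(object@blockChrom) != B || length(object@blockStart) != B ||
      length(object@blockEnd) != B)
    return("block annotations must have one entry per block")
  r <- object@blockRecomb
  if (length(r) != B - 1L) return("blockRecomb must have B - 1 entries")
  if (length(r) && (any(!is.finite(r)) || any(r < 0) || any(r > 0.5)))
    return("blockRecomb must lie in [0, 0.5]")
  bnd <- which(diff(object@blockChrom) != 0L)
  if (length(bnd) && any(r[bnd] != 0.5))
    return("chromosome-boundary gaps must have blockRecomb = 0.5")
  if (is.null(colnames(s1))) return("individual ids must be column names")
  TRUE
})

#' Parameters of the stochastic look-ahead objective
#'
#' @slot W positive integer; look-ahead window length in generations
#'   (for LAS this is replaced by the remaining horizon T - t).
#' @slot lambda numeric >= 0; per-generation discount rate expressing the
#'   time value of genetic gain.
#' @slot gamma numeric in (0, 1); quantile/risk parameter. The objective
#'   uses the gamma quantile of a random descendant progeny's GEBV.
#' @slot K positive integer; Monte-Carlo progeny sample count.
#'
#' @seealso [LookAheadSpec()], [pvlasObjective()], [lasObjective()]
#' @exportClass LookAheadSpec
setClass("LookAheadSpec",
  representation(W = "integer", lambda = "numeric", gamma = "numeric",
    K = "integer"))

setValidity("LookAheadSpec", function(object) {
  if (object@W < 1L) return("W must be >= 1")
  if (!is.finite(object@lambda) || object@lambda < 0)
    return("lambda must be >= 0")
  if (!is.finite(object@gamma) || object@gamma <= 0 || object@gamma >= 1)
    return("gamma must lie in (0, 1)")
  if (object@K < 1L) return("K must be >= 1")
  TRUE
})

#' A mating plan of S unordered crosses
#'
#' Normalized as a list of S unordered parent pairs (selfing allowed);
#' the equivalent selection vector x and symmetric mating matrix Y of the
#' integer-programming formulation are derived by [selectionVector()] and
#' [matingMatrix()].
#'
#' @slot pairs integer S x 2 matrix with each row an unordered pair
#'   (stored with pairs\[ ,1\] <= pairs\[ ,2\]).
#' @slot nInd integer; population size N the indices refer to.
#'
#' @seealso [MatingPlan()], [checkFeasibility()], [localSearch()]
#' @exportClass MatingPlan
setClass("MatingPlan", representation(pairs = "matrix", nInd = "integer"))

setValidity("MatingPlan", function(object) {
  p <- object@pairs
  if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 1L)
    return("pairs must be an S x 2 matrix with S >= 1")
  if (any(p < 1L) || any(p > object@nInd))
    return("pair indices must lie in 1..N")
  if (any(p[, 1L] > p[, 2L]))
    return("pairs must be stored unordered with first index <= second")
  key <- paste(p[, 1L], p[, 2L])
  if (anyDuplicated(key)) return("duplicate crosses are not allowed")
  TRUE
})

#' Per-generation best GEBVs with a discount rate
#'
#' Records the maximum individual GEBV attained in each completed
#' generation of a breeding program, together with the discount rate used
#' to aggregate them into a present value.
#'
#' @slot perGenerationBest numeric vector of length T (trait units).
#' @slot lambda numeric >= 0; per-generation discount rate.
#'
#' @seealso [GainLedger()], [presentValueOfGains()]
#' @exportClass GainLedger
setClass("GainLedger",
  representation(perGenerationBest = "numeric", lambda = "numeric"))

setValidity("GainLedger", function(object) {
  if (length(object@perGenerationBest) < 1L ||
      any(!is.finite(object@perGenerationBest)))
    return("perGenerationBest must be non-empty and finite")
  if (!is.finite(object@lambda) || object@lambda < 0)
    return("lambda must be >= 0")
  TRUE
})

#' Value of a stochastic look-ahead objective
#'
#' Holds the per-offset gamma-quantiles psi_tau together with the scalar
#' objective: zeta (PV-LAS, discounted sum of psi) or phi (LAS, terminal
#' quantile).
#'
#' @slot zeta numeric scalar or NA; the PV-LAS objective.
#' @slot phi numeric scalar or NA; the LAS objective.
#' @slot psi numeric vector; gamma-quantile of the simulated progeny GEBV
#'   distribution at each look-ahead offset tau.
#' @slot lambda numeric; discount rate used for zeta.
#'
#' @seealso [pvlasObjective()], [lasObjective()]
#' @exportClass ObjectiveValue
setClass("ObjectiveValue",
  representation(zeta = "numeric", phi = "numeric", psi = "numeric",
    lambda = "numeric"))

setValidity("ObjectiveValue", function(object) {
  if (!is.na(object@zeta)) {
    w <- (1 + object@lambda)^seq_along(object@psi)
    if (abs(object@zeta - sum(object@psi / w)) > 1e-9)
      return("zeta must equal sum(psi / (1 + lambda)^tau)")
  }
  TRUE
})
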