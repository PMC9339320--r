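#' Genomic estimated breeding values
#'
#' Computes \eqn{v_i = \mu + \sum_l \beta_l (G_{l,1,i} + G_{l,2,i})} for
#' every individual: the additive model underlying all selection criteria
#' in this package. For a [BlockedPopulation-class] the block scores
#' already embed the effects, so no trait model is needed.
#'
#' @param x a [PhasedGenotypes-class] or [BlockedPopulation-class] object.
#' @param trait a [TraitModel-class] (required for phased genotypes).
#' @param ... unused.
#' @return Named numeric vector of length N, in trait units.
#' @examples
#' g <- PhasedGenotypes(matrix(c(1L, 1L), 2, 1), matrix(c(1L, 0L), 2, 1))
#' gebv(g, TraitModel(c(1, 2)))  # 1*2 + 2*1 = 4
#' @name gebv
NULL

#' @rdname gebv
setMethod("gebv", c("PhasedGenotypes", "TraitModel"), function(x, trait, ...) {
  beta <- trait@beta
  if (length(beta) != nLoci(x))
    argError("beta has %d effects but genotypes have %d loci",
             length(beta), nLoci(x))
  v <- trait@mu + drop(crossprod(x@hap1 + x@hap2, beta))
  names(v) <- indIds(x)
  v
})

#' @rdname gebv
setMethod("gebv", c("BlockedPopulation", "missing"), function(x, trait, ...) {
  v <- x@mu + colSums(x@scores1) + colSums(x@scores2)
  names(v) <- indIds(x)
  v
})

#' Genetic potential of a population
#'
#' Theoretical bounds on the GEBV reachable from the alleles still
#' segregating in the population, a proxy for retained genetic diversity:
#' `lowerPotential` returns \eqn{2\sum_l \min_{m,i} G_{l,m,i}\beta_l} and
#' `upperPotential` returns \eqn{2\sum_l \max_{m,i} G_{l,m,i}\beta_l}.
#' The overall mean is excluded; the bounds assume homozygosity at the
#' per-locus extreme is reachable, so for every individual
#' `lowerPotential <= v_i - mu <= upperPotential`.
#'
#' @inheritParams gebv
#' @return A single number in trait units.
#' @name potentials
NULL

#' @rdname potentials
setMethod("lowerPotential", c("PhasedGenotypes", "TraitModel"),
  function(x, trait, ...) {
    beta <- trait@beta
    if (length(beta) != nLoci(x))
      argError("beta/loci dimension mismatch")
    2 * sum(pmin(rowMins(x@hap1), rowMins(x@hap2)) * pmax(beta, 0) +
            pmax(rowMaxs(x@hap1), rowMaxs(x@hap2)) * pmin(beta, 0))
  })

#' @rdname potentials
setMethod("upperPotential", c("PhasedGenotypes", "TraitModel"),
  function(x, trait, ...) {
    beta <- trait@beta
    if (length(beta) != nLoci(x))
      argError("beta/loci dimension mismatch")
    2 * sum(pmax(rowMaxs(x@hap1), rowMaxs(x@hap2)) * pmax(beta, 0) +
            pmin(rowMins(x@hap1), rowMins(x@hap2)) * pmin(beta, 0))
  })

#' @rdname potentials
setMethod("lowerPotential", c("BlockedPopulation", "missing"),
  function(x, trait, ...) {
    2 * sum(pmin(rowMins(x@scores1), rowMins(x@scores2)))
  })

#' @rdname potentials
setMethod("upperPotential", c("BlockedPopulation", "missing"),
  function(x, trait, ...) {
    2 * sum(pmax(rowMaxs(x@scores1), rowMaxs(x@scores2)))
  })

#' Present value of a sequence of genetic gains
#'
#' Discounts the best GEBV attained in each generation back to generation
#' 0: \eqn{\sum_{\tau=1}^{T} b_\tau / (1+\lambda)^\tau}. This is both the
#' program-evaluation criterion and the aggregation used inside the PV-LAS
#' objective.
#'
#' @param best a [GainLedger-class] object, or a numeric vector of
#'   per-generation best GEBVs.
#' @param lambda per-generation discount rate (ignored when `best` is a
#'   GainLedger, which carries its own).
#' @return A single number, in discounted trait units.
#' @examples
#' presentValueOfGains(c(1.1, 1.21), lambda = 0.1)  # 2
#' @export
presentValueOfGains <- function(best, lambda = 0.1) {
  if (is(best, "GainLedger")) {
    lambda <- best@lambda
    best <- best@perGenerationBest
  }
  if (length(best) < 1L) argError("empty gain sequence")
  if (!is.finite(lambda) || lambda < 0) argError("lambda must be >= 0")
  sum(best / (1 + lambda)^seq_along(best))
}

# Deterministic block partition: allocate nBlocks across chromosomes by
# largest-remainder proportional shares (at least 1 and at most Lc blocks
# per chromosome), then equal-count contiguous ranges within a chromosome
# with remainder loci going to the earliest blocks.
blockPartition <- function(chrom, nBlocks) {
  L <- length(chrom)
  chroms <- unique(chrom)
  Lc <- as.integer(table(factor(chrom, levels = chroms)))
  nc <- length(chroms)
  if (nBlocks < nc)
    argError("n_blocks (%d) is below the number of chromosomes (%d)",
             nBlocks, nc)
  if (nBlocks > L) argError("n_blocks (%d) exceeds the locus count (%d)",
                            nBlocks, L)
  share <- nBlocks * Lc / L
  alloc <- pmax(1L, pmin(Lc, as.integer(floor(share))))
  while (sum(alloc) != nBlocks) {
    if (sum(alloc) < nBlocks) {
      room <- which(alloc < Lc)
      pick <- room[order(-(share[room] - alloc[room]), room)][1L]
      alloc[pick] <- alloc[pick] + 1L
    } else {
      room <- which(alloc > 1L)
      pick <- room[order(share[room] - alloc[room], room)][1L]
      alloc[pick] <- alloc[pick] - 1L
    }
  }
  start <- integer(0); end <- integer(0); bchrom <- integer(0)
  off <- 0L
  for (c in seq_len(nc)) {
    nb <- alloc[c]
    sz <- rep(Lc[c] %/% nb, nb)
    extra <- Lc[c] %% nb
    if (extra > 0L) sz[seq_len(extra)] <- sz[seq_len(extra)] + 1L
    e <- off + cumsum(sz)
    s <- c(off + 1L, utils::head(e, -1L) + 1L)
    start <- c(start, s); end <- c(end, e)
    bchrom <- c(bchrom, rep(chroms[c], nb))
    off <- off + Lc[c]
  }
  list(start = as.integer(start), end = as.integer(end),
       chrom = as.integer(bchrom))
}

#' Aggregate SNPs into recombination blocks
#'
#' Reduces an L-locus phased population to B contiguous blocks per
#' chromosome (equal locus counts per block as far as possible, remainder
#' loci to the earliest blocks). Each block haplotype carries the score
#' \eqn{\sum_{l \in b} \beta_l G_{l,m,i}} and is subsequently inherited
#' atomically, the standard optimal-haploid-value style speed-up. GEBVs
#' are preserved exactly. The recombination frequency between adjacent
#' blocks on the same chromosome aggregates the intervals between the two
#' blocks' midpoint loci as \eqn{1 - \prod_l (1 - r_l)} (capped at 0.5);
#' chromosome boundaries keep r = 0.5.
#'
#' @param x a [PhasedGenotypes-class] population.
#' @param trait a [TraitModel-class] with one effect per locus.
#' @param map a [GeneticMap-class] over the same loci.
#' @param nBlocks number of blocks B, with
#'   `nChrom(map) <= nBlocks <= nLoci(x)`. `nBlocks = nLoci(x)` gives the
#'   identity partition (block scores `beta * allele`, block recomb = r).
#' @return A [BlockedPopulation-class] object.
#' @export
aggregateBlocks <- function(x, trait, map, nBlocks) {
  stopifnot(is(x, "PhasedGenotypes"), is(trait, "TraitModel"),
            is(map, "GeneticMap"))
  L <- nLoci(x)
  if (length(trait@beta) != L || nLoci(map) != L)
    argError("trait/map/genotypes disagree on locus count")
  part <- blockPartition(map@chrom, as.integer(nBlocks))
  B <- length(part$start)
  grp <- rep(seq_len(B), part$end - part$start + 1L)
  s1 <- rowsum(x@hap1 * trait@beta, grp, reorder = TRUE)
  s2 <- rowsum(x@hap2 * trait@beta, grp, reorder = TRUE)
  rownames(s1) <- rownames(s2) <- NULL
  colnames(s1) <- colnames(s2) <- indIds(x)
  mid <- part$start + (part$end - part$start) %/% 2L
  br <- numeric(max(B - 1L, 0L))
  r <- map@recomb
  for (b in seq_len(max(B - 1L, 0L))) {
    if (part$chrom[b] != part$chrom[b + 1L]) {
      br[b] <- 0.5
    } else {
      span <- seq.int(mid[b], mid[b + 1L] - 1L)
      br[b] <- min(0.5, 1 - prod(1 - r[span]))
    }
  }
  new("BlockedPopulation", scores1 = s1, scores2 = s2,
      blockChrom = part$chrom, blockStart = part$start,
      blockEnd = part$end, blockRecomb = br, mu = trait@mu,
      generation = x@generation)
}
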