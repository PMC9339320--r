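#' Sample gametes from one diploid parent
#'
#' Meiosis under a first-order Markov (Haldane, no-interference) model:
#' the source haplotype at the first locus is uniform over the two
#' parental haplotypes and switches at interval l with probability
#' \eqn{r_l}, independently across intervals; the gamete copies the
#' current source's allele at every locus. `sampleGamete()` returns a
#' single gamete, `sampleGametes()` an L x n matrix of n independent
#' gametes.
#'
#' @param hap1,hap2 numeric/integer vectors of length L (the parent's two
#'   haplotypes; 0/1 alleles, or block scores).
#' @param map a [GeneticMap-class], or a numeric vector of L - 1
#'   recombination frequencies.
#' @param n number of gametes.
#' @return `sampleGamete()`: a vector of length L; `sampleGametes()`: an
#'   L x n matrix. Every entry equals one of the parental values at that
#'   locus (mosaic conservation).
#' @examples
#' set.seed(1)
#' sampleGamete(c(1, 1, 0), c(0, 0, 1), GeneticMap(c(0.1, 0.2)))
#' @export
sampleGametes <- function(hap1, hap2, map, n = 1L) {
  r <- if (is(map, "GeneticMap")) map@recomb else as.numeric(map)
  L <- length(hap1)
  if (length(hap2) != L || length(r) != L - 1L)
    argError("haplotype length %d needs a map of %d intervals", L, L - 1L)
  .cppMeiosisGametes(as.numeric(hap1), as.numeric(hap2), r, as.integer(n))
}

#' @rdname sampleGametes
#' @export
sampleGamete <- function(hap1, hap2, map) {
  drop(sampleGametes(hap1, hap2, map, 1L))
}

#' Exact gamete distribution of one meiosis
#'
#' Exhaustively enumerates the 2^L source paths of the Markov
#' recombination chain and aggregates identical output haplotypes. This is
#' the exact counterpart of [sampleGamete()], intended as an independent
#' oracle for validating the sampler.
#'
#' @inheritParams sampleGametes
#' @param maxLoci enumeration guard; L must not exceed it (default 16).
#' @return A data.frame with one row per distinct gamete: columns
#'   `haplotype` (alleles pasted with "/") and `prob`. Probabilities sum
#'   to 1.
#' @export
enumerateGameteDistribution <- function(hap1, hap2, map, maxLoci = 16L) {
  r <- if (is(map, "GeneticMap")) map@recomb else as.numeric(map)
  L <- length(hap1)
  if (L > maxLoci)
    argError("enumeration over 2^%d source paths refused (L > %d)", L, maxLoci)
  if (length(hap2) != L || length(r) != L - 1L)
    argError("haplotype length %d needs a map of %d intervals", L, L - 1L)
  nPaths <- 2^L
  probs <- new.env(parent = emptyenv())
  for (p in seq_len(nPaths) - 1L) {
    src <- as.integer(intToBits(p))[seq_len(L)]
    pr <- 0.5
    if (L > 1L) {
      sw <- src[-1L] != src[-L]
      pr <- pr * prod(ifelse(sw, r, 1 - r))
    }
    if (pr == 0) next
    out <- ifelse(src == 1L, hap2, hap1)
    key <- paste(out, collapse = "/")
    probs[[key]] <- (probs[[key]] %||% 0) + pr
  }
  keys <- sort(ls(probs))
  data.frame(haplotype = keys,
             prob = vapply(keys, function(k) probs[[k]], numeric(1)),
             row.names = NULL)
}

#' Produce progeny from one cross
#'
#' Each progeny receives one independently sampled gamete from each
#' parent (two independent gametes from the same parent under selfing).
#' The generation index is incremented.
#'
#' @param x a [PhasedGenotypes-class] or [BlockedPopulation-class]
#'   population holding the parents.
#' @param pair length-2 vector of parent indices (i, j); i = j is selfing.
#' @param nProgeny number of progeny to produce.
#' @param map a [GeneticMap-class] (ignored for a blocked population,
#'   which carries its own inter-block map).
#' @param ids optional progeny ids.
#' @param ... unused.
#' @return A population of the same class with `nProgeny` individuals.
#' @name makeProgeny
NULL

#' @rdname makeProgeny
setMethod("makeProgeny", "PhasedGenotypes",
  function(x, pair, nProgeny, map, ids = NULL, ...) {
    i <- pair[1L]; j <- pair[2L]
    r <- map@recomb
    g1 <- .cppMeiosisGametes(as.numeric(x@hap1[, i]), as.numeric(x@hap2[, i]),
                             r, as.integer(nProgeny))
    g2 <- .cppMeiosisGametes(as.numeric(x@hap1[, j]), as.numeric(x@hap2[, j]),
                             r, as.integer(nProgeny))
    if (is.null(ids))
      ids <- sprintf("g%d_%dx%d_%d", x@generation + 1L, i, j,
                     seq_len(nProgeny))
    PhasedGenotypes(g1, g2, ids = ids, generation = x@generation + 1L)
  })

#' @rdname makeProgeny
setMethod("makeProgeny", "BlockedPopulation",
  function(x, pair, nProgeny, map, ids = NULL, ...) {
    i <- pair[1L]; j <- pair[2L]
    r <- x@blockRecomb
    g1 <- .cppMeiosisGametes(x@scores1[, i], x@scores2[, i], r,
                             as.integer(nProgeny))
    g2 <- .cppMeiosisGametes(x@scores1[, j], x@scores2[, j], r,
                             as.integer(nProgeny))
    if (is.null(ids))
      ids <- sprintf("g%d_%dx%d_%d", x@generation + 1L, i, j,
                     seq_len(nProgeny))
    colnames(g1) <- colnames(g2) <- ids
    new("BlockedPopulation", scores1 = g1, scores2 = g2,
        blockChrom = x@blockChrom, blockStart = x@blockStart,
        blockEnd = x@blockEnd, blockRecomb = r, mu = x@mu,
        generation = x@generation + 1L)
  })

#' Generation-inflated recombination frequencies
#'
#' Effective recombination frequency experienced by a descendant tau
#' generations ahead when S crosses are made per generation:
#' \deqn{\tilde R_l = 0 \textrm{ for } \tau \in \{1,2\}; \quad
#'   \tilde R_l = (S-1)\,[1-(1-r_l)^\tau]/S \textrm{ for } \tau \ge 3.}
#' The value is the between-cross mixing probability of the look-ahead
#' descendant-gamete chain; it is non-decreasing in tau (for tau >= 3)
#' and bounded by (S-1)/S.
#'
#' @param map a [GeneticMap-class] or numeric vector of recombination
#'   frequencies.
#' @param tau generation offset, >= 1.
#' @param S number of crosses per generation, >= 1.
#' @return Numeric vector of the same length as the input frequencies.
#' @examples
#' lookaheadRecomb(0.1, tau = 3, S = 10)  # 9 * (1 - 0.9^3) / 10
#' @export
lookaheadRecomb <- function(map, tau, S) {
  r <- if (is(map, "GeneticMap")) map@recomb else as.numeric(map)
  tau <- as.integer(tau); S <- as.integer(S)
  if (tau < 1L) argError("tau must be >= 1")
  if (S < 1L) argError("S must be >= 1")
  if (tau <= 2L) return(numeric(length(r)))
  (S - 1) * (1 - (1 - r)^tau) / S
}

# Build the loci/blocks x 4S pool matrix of per-locus values for a mating
# plan: columns 4s-3..4s are the four haplotypes of cross s (a selfing
# cross contributes its parent's two haplotypes twice, so a selfing-only
# plan never imports foreign alleles).
crossPool <- function(s1, s2, pairs) {
  S <- nrow(pairs)
  cols <- matrix(0, nrow(s1), 4L * S)
  for (s in seq_len(S)) {
    i <- pairs[s, 1L]; j <- pairs[s, 2L]
    cols[, 4L * s - 3L] <- s1[, i]
    cols[, 4L * s - 2L] <- s2[, i]
    cols[, 4L * s - 1L] <- s1[, j]
    cols[, 4L * s] <- s2[, j]
  }
  cols
}

# Normalize a population + trait/map into the score representation used by
# the objective and look-ahead machinery: per-haplotype value matrices
# (beta * allele, or block scores), a recombination vector and mu.
scoreState <- function(x, trait = NULL, map = NULL) {
  if (is(x, "BlockedPopulation")) {
    list(s1 = x@scores1, s2 = x@scores2, r = x@blockRecomb, mu = x@mu)
  } else {
    stopifnot(is(x, "PhasedGenotypes"), is(trait, "TraitModel"),
              is(map, "GeneticMap"))
    if (length(trait@beta) != nLoci(x) || nLoci(map) != nLoci(x))
      argError("trait/map/genotypes disagree on locus count")
    list(s1 = x@hap1 * trait@beta, s2 = x@hap2 * trait@beta,
         r = map@recomb, mu = trait@mu)
  }
}

#' Simulate GEBVs of descendant progeny under a mating plan
#'
#' Look-ahead simulation of a random progeny tau generations ahead of the
#' current population when the S crosses of `crosses` are made. A progeny
#' is two independent descendant gametes. At tau = 1 each gamete is a
#' single meiosis from one parent of a uniformly chosen cross. At
#' tau >= 2 each gamete is a Markov mosaic over the 4S haplotypes of the
#' plan: at interval l the chain migrates to a uniformly chosen haplotype
#' of a different cross with probability \eqn{\tilde R_l(\tau)}
#' ([lookaheadRecomb()]; zero for tau < 3) and otherwise switches to one
#' of the other three haplotypes of its current cross with probability
#' \eqn{1-(1-r_l)^\tau}; effective switch probabilities are capped at
#' 0.5.
#'
#' @param x a [PhasedGenotypes-class] or [BlockedPopulation-class].
#' @param crosses a [MatingPlan-class] (or S x 2 pair matrix).
#' @param tau generation offset >= 1.
#' @param trait,map required when `x` is a PhasedGenotypes.
#' @param K number of simulated progeny.
#' @return Numeric vector of K simulated progeny GEBVs (trait units,
#'   including the overall mean). Every sample lies within the potential
#'   bounds computed from the selected parents' haplotypes alone.
#' @export
simulateDescendantProgeny <- function(x, crosses, tau, trait = NULL,
                                      map = NULL, K = 500L) {
  pairs <- if (is(crosses, "MatingPlan")) crosses@pairs else
    matrix(as.integer(crosses), ncol = 2L)
  if (nrow(pairs) < 1L) argError("need at least one cross")
  tau <- as.integer(tau)
  if (tau < 1L) argError("tau must be >= 1")
  st <- scoreState(x, trait, map)
  pool <- crossPool(st$s1, st$s2, pairs)
  segs <- .cppSampleSegments(st$r, nrow(pairs), tau, as.integer(K))
  st$mu + .cppSegmentScores(pool, segs$gamStart, segs$segEnd, segs$segCol)
}
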