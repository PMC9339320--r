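#' Generate a synthetic founder panel
#'
#' Draws phased alleles independently per locus with a locus-specific
#' major-allele frequency. By default founders are fully homozygous
#' (inbred lines, as in maize breeding material): haplotype 1 is drawn and
#' copied to haplotype 2. No linkage disequilibrium is simulated.
#'
#' @param N number of individuals.
#' @param L number of loci.
#' @param chromCount number of chromosomes (unused here beyond sanity; the
#'   map carries the partition).
#' @param alleleFreq major-allele frequency: a single value, a vector of
#'   length L, or NULL to draw p_l ~ Uniform(0.1, 0.9) per locus.
#' @param inbred copy haplotype 1 to haplotype 2 (default TRUE).
#' @return A [PhasedGenotypes-class] founder panel (generation 0).
#' @export
generateFounders <- function(N, L, chromCount = 1L, alleleFreq = NULL,
                             inbred = TRUE) {
  if (N < 1L || L < 1L || chromCount < 1L)
    argError("N, L and chromCount must be >= 1")
  p <- if (is.null(alleleFreq)) runif(L, 0.1, 0.9) else
    rep_len(as.numeric(alleleFreq), L)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    argError("allele frequencies must lie in [0, 1]")
  h1 <- matrix(rbinom(L * N, 1L, rep(p, N)), nrow = L)
  h2 <- if (inbred) h1 else matrix(rbinom(L * N, 1L, rep(p, N)), nrow = L)
  PhasedGenotypes(h1, h2, ids = paste0("f", seq_len(N)), generation = 0L)
}

#' Generate sparse additive marker effects
#'
#' Each effect is nonzero with probability `sparsity` and then drawn from
#' a zero-mean normal with standard deviation `scale`, giving the sparse
#' mixed-sign architecture the selection algorithms assume. When L >= 20
#' and sparsity > 0, the draw is repeated until both positive and
#' negative effects are present.
#'
#' @param L number of loci.
#' @param sparsity probability that a locus has a nonzero effect
#'   (default 0.1).
#' @param scale standard deviation of nonzero effects (default 1).
#' @param mu overall mean (default 0).
#' @return A [TraitModel-class].
#' @export
generateEffects <- function(L, sparsity = 0.1, scale = 1, mu = 0) {
  if (L < 1L) argError("L must be >= 1")
  if (sparsity < 0 || sparsity > 1) argError("sparsity must lie in [0, 1]")
  draw <- function() {
    nz <- runif(L) < sparsity
    beta <- numeric(L)
    beta[nz] <- rnorm(sum(nz), 0, scale)
    beta
  }
  beta <- draw()
  if (sparsity > 0 && L >= 20L) {
    while (!any(beta > 0) || !any(beta < 0)) beta <- draw()
  }
  TraitModel(beta, mu = mu)
}

#' Generate a synthetic genetic map
#'
#' Splits L loci evenly across chromosomes (earlier chromosomes take the
#' remainder) and draws within-chromosome recombination frequencies
#' i.i.d. uniform on (0, 2 * meanR], capped at 0.5; chromosome-boundary
#' intervals carry r = 0.5.
#'
#' @param L number of loci.
#' @param chromCount number of chromosomes.
#' @param meanR mean within-chromosome recombination frequency,
#'   in (0, 0.5].
#' @return A [GeneticMap-class].
#' @export
generateMap <- function(L, chromCount = 1L, meanR = 0.1) {
  if (L < 1L || chromCount < 1L || chromCount > L)
    argError("need 1 <= chromCount <= L")
  if (!is.finite(meanR) || meanR <= 0 || meanR > 0.5)
    argError("meanR must lie in (0, 0.5]")
  sz <- rep(L %/% chromCount, chromCount)
  extra <- L %% chromCount
  if (extra > 0L) sz[seq_len(extra)] <- sz[seq_len(extra)] + 1L
  chrom <- rep(seq_len(chromCount), sz)
  r <- numeric(max(L - 1L, 0L))
  if (L > 1L) {
    r <- pmin(0.5, runif(L - 1L, 0, 2 * meanR))
    r[diff(chrom) != 0L] <- 0.5
  }
  GeneticMap(r, chrom)
}

#' The fixed illustrative toy instance
#'
#' A deterministic small instance with the dimensions of the published
#' illustrative example: S = 3 crosses from N = 8 diploid individuals
#' genotyped at L = 10 SNPs on one chromosome, a three-generation
#' deadline/window (T = W = 3), K = 500 simulated progeny and
#' gamma = 0.8. The genotype, effect and map values are fixed arbitrary
#' stand-ins generated from an internal seed (the original example's
#' values are only published graphically).
#'
#' @return List with elements `genotypes` ([PhasedGenotypes-class]),
#'   `trait` ([TraitModel-class]), `map` ([GeneticMap-class]), `S`, and
#'   `spec` ([LookAheadSpec-class] with W = 3, lambda = 0.1, gamma = 0.8,
#'   K = 500).
#' @export
toyExample <- function() {
  withSeed(20220602L, {
    geno <- generateFounders(8L, 10L, 1L, inbred = TRUE)
    beta <- round(rnorm(10L, 0, 1), 2)
    beta[sample.int(10L, 2L)] <- 0
    trait <- TraitModel(beta, mu = 0)
    map <- generateMap(10L, 1L, meanR = 0.15)
    list(genotypes = geno, trait = trait, map = map, S = 3L,
         spec = LookAheadSpec(W = 3L, lambda = 0.1, gamma = 0.8, K = 500L))
  })
}
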