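# Shared fixtures and independent oracles.

# small random heterozygous population + trait + map, deterministic
makeInstance <- function(N, L, nChrom = 1L, seed = 1L, inbred = FALSE) {
  withr::with_seed(seed, {
    h1 <- matrix(rbinom(L * N, 1L, 0.5), L, N)
    h2 <- if (inbred) h1 else matrix(rbinom(L * N, 1L, 0.5), L, N)
    geno <- PhasedGenotypes(h1, h2, ids = sprintf("i%d", seq_len(N)))
    beta <- rnorm(L)
    chrom <- sort(rep_len(seq_len(nChrom), L))
    r <- runif(max(L - 1L, 0L), 0, 0.3)
    map <- GeneticMap(r, chrom)   # boundaries forced to 0.5
    list(geno = geno, trait = TraitModel(beta), map = map)
  })
}

# total-variation distance between an empirical sample of gametes
# (L x n matrix) and the exact enumeration table
tvDistance <- function(gametes, exact) {
  keys <- apply(gametes, 2L, paste, collapse = "/")
  emp <- table(keys) / ncol(gametes)
  all <- union(names(emp), exact$haplotype)
  pe <- ifelse(all %in% names(emp), as.numeric(emp[all]), 0)
  px <- exact$prob[match(all, exact$haplotype)]
  px[is.na(px)] <- 0
  sum(abs(pe - px)) / 2
}

# Exact expected GEBV (minus intercept) of a descendant progeny, by
# dynamic programming over the 4S-state look-ahead chain; independent of
# the C++ sampler. tau = 1 uses the closed form (each gamete's marginal
# source is uniform at every locus).
dpDescendantMean <- function(pool, r, S, tau) {
  B <- nrow(pool)
  if (tau == 1L) return(2 * mean(colSums(pool)))
  nState <- 4L * S
  p <- rep(1 / nState, nState)
  ev <- sum(p * pool[1L, ])
  if (B > 1L) for (l in seq_len(B - 1L)) {
    w <- 1 - (1 - r[l])^tau
    q <- min(w, 0.5)
    Rl <- if (S > 1L && tau >= 3L) min((S - 1) * w / S, 0.5) else 0
    Tm <- matrix(0, nState, nState)
    for (a in seq_len(nState)) {
      ca <- (a - 1L) %/% 4L
      for (b in seq_len(nState)) {
        cb <- (b - 1L) %/% 4L
        Tm[a, b] <- if (a == b) (1 - Rl) * (1 - q)
        else if (ca == cb) (1 - Rl) * q / 3
        else Rl / (4 * (S - 1))
      }
    }
    p <- drop(p %*% Tm)
    ev <- ev + sum(p * pool[l + 1L, ])
  }
  2 * ev
}

# pool matrix of beta*allele haplotype values for a pair list (mirrors the
# package's internal layout, rebuilt here from public accessors)
poolFromPlan <- function(geno, trait, pairs) {
  s1 <- haplotypes(geno, 1L) * markerEffects(trait)
  s2 <- haplotypes(geno, 2L) * markerEffects(trait)
  do.call(cbind, lapply(seq_len(nrow(pairs)), function(s) {
    i <- pairs[s, 1L]; j <- pairs[s, 2L]
    cbind(s1[, i], s2[, i], s1[, j], s2[, j])
  }))
}

# deterministic plan objective used where the tests need a noise-free
# objective: sum over crosses of the best haploid value attainable from
# the four parental haplotypes (an optimal-haploid-value style score)
ohvObjective <- function(geno, trait) {
  s1 <- haplotypes(geno, 1L) * markerEffects(trait)
  s2 <- haplotypes(geno, 2L) * markerEffects(trait)
  function(plan) {
    p <- crossPairs(plan)
    sum(vapply(seq_len(nrow(p)), function(s) {
      m <- cbind(s1[, p[s, 1L]], s2[, p[s, 1L]], s1[, p[s, 2L]],
                 s2[, p[s, 2L]])
      2 * sum(apply(m, 1L, max))
    }, numeric(1)))
  }
}
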