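---
title: "Present-value look-ahead genomic selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Present-value look-ahead genomic selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvlas)
```

## The selection problem

A genomic-selection breeding program holds, in each generation, a
population of N diploid individuals genotyped at L ordered biallelic
markers. Under the additive model, the genomic estimated breeding value
(GEBV) of individual i is

$$v_i = \mu + \sum_{l=1}^{L} \beta_l \,(G_{l,1,i} + G_{l,2,i}),$$

where $G_{l,m,i} \in \{0,1\}$ is the allele on haplotype m and
$\beta_l$ the additive effect of one copy of the major allele (trait
units per allele copy). Effects and the recombination map are inputs:
this package does not estimate them, and dominance, epistasis and
genotype-by-environment interaction are out of scope.

Each cycle, S crosses are chosen (a selection vector x and a symmetric
mating matrix Y, normalized here as a list of S unordered parent pairs;
selfing is allowed, as is natural for inbred-line crops). Each cross
contributes N/S progeny to the next generation. Three strategies are
implemented:

* **CGS** (conventional genomic selection): the 2S individuals with the
  highest GEBVs, randomly mated by a uniform perfect matching.
* **LAS** (look-ahead selection): crosses maximizing $\varphi$, the
  $\gamma$-quantile of the GEBV of a random progeny simulated at the
  program deadline, i.e. at the shrinking horizon $T - t$.
* **PV-LAS** (present-value look-ahead selection): crosses maximizing
  $\zeta = \sum_{\tau=1}^{W} \psi_\tau / (1+\lambda)^\tau$, the
  discounted sum of the $\gamma$-quantiles $\psi_\tau$ of a random
  progeny's GEBV over a sliding window of W future generations. The
  discount rate $\lambda$ (per generation, dimensionless) expresses the
  time value of genetic gain: gain arriving $\tau$ generations from now
  is worth $(1+\lambda)^{-\tau}$ of the same gain today.

The asymmetry between LAS and PV-LAS is deliberate and hard-coded: LAS
plans toward a fixed deadline, PV-LAS always looks W generations ahead.

## Meiosis and the look-ahead simulation

Gametes follow a first-order Markov (Haldane, no-interference) model:
the source haplotype starts uniform and switches between the two
parental haplotypes at interval l with probability $r_l \in [0, 0.5]$;
chromosome boundaries carry $r = 0.5$. `enumerateGameteDistribution()`
enumerates the $2^L$ source paths exactly and serves as the oracle for
validating the sampler; total-variation agreement is asserted in the
test suite at 100,000 draws.

A progeny $\tau$ generations ahead of a mating plan is simulated as two
independent descendant gametes. At $\tau = 1$ a progeny is one meiosis
from each parent of a uniformly chosen cross. At $\tau \ge 2$ each
gamete is a Markov mosaic over the plan's 4S haplotypes: at interval l
it migrates to a uniformly chosen haplotype of a *different* cross with
the inflated probability

$$\tilde R_l = \begin{cases} 0, & \tau \in \{1, 2\} \\
\dfrac{(S-1)\,[1-(1-r_l)^\tau]}{S}, & \tau \ge 3, \end{cases}$$

and otherwise switches to one of the other three haplotypes of its
current cross with probability $1-(1-r_l)^\tau$ (both effective
probabilities capped at 0.5, since a recombination fraction cannot
exceed independent assortment). This construction reproduces single
meiosis at $\tau = 1$, accumulates within-cross recombination as
$1-(1-r)^\tau$, and introduces between-cross mixing exactly when
$\tilde R$ is nonzero. Two choices here were genuinely open and are
fixed as follows: a selfing pair contributes its parent's two
haplotypes twice to the pool (a selfing-only plan never imports foreign
alleles), and the within-cross switch targets the three alternatives
uniformly.

$\psi_\tau$ is the empirical $\gamma$-quantile of K simulated progeny
GEBVs, defined as the ascending order statistic at rank
$\lceil \gamma K \rceil$ — no interpolation, so results are exactly
reproducible and the degenerate case (selfing a fully homozygous
parent) returns the parent's GEBV without tolerance. The quantile is
taken over a *random* progeny of the plan (the probabilistic constraint
defining $\psi$), not over the best of a batch.

## Optimization

Plans are optimized by a pair-replacement local search. Starting from a
feasible warm start (top-2S GEBV individuals paired by rank), each pass
visits every (cross, parent-slot) in random order, evaluates all
feasible replacement parents k in 1..N, and accepts the best strictly
improving neighbor. The search repeats passes until one yields no
improvement (with a generous safety cap of 40 passes); termination at
local optimality matches the published procedure for this family of
heuristics. An exhaustive enumerator over all S-subsets of unordered
pairs provides ground truth on small instances; the suite requires the
local search to reach at least 95% of the exhaustive optimum in 18 of
20 random instances at N = 8, S = 2.

Stochastic objectives are compared under common random numbers, which
this implementation realizes by construction: the recombination
trajectory of a descendant gamete (which cross and haplotype slot it
copies at each block) depends only on (r, S, $\tau$), never on which
individuals occupy the plan. One frozen draw of K trajectories per
offset therefore serves every candidate plan in a search, making the
objective deterministic within a search and the monotone-acceptance
guarantee exact. A single frozen draw is used for the entire search
(not one per pass): this makes "the returned plan is at least as good
as the start" a theorem rather than an approximation, at the cost of
optimizing a fixed sample-average approximation of the objective.
Candidate evaluation is incremental: neighbors differ in one cross, so
only trajectory segments copying from the modified cross are re-scored.

## Block aggregation

For long marker panels, `aggregateBlocks()` reduces the L loci to B
contiguous blocks per chromosome (equal locus counts as far as
possible, remainder to the earliest blocks; block counts allocated to
chromosomes by largest-remainder shares). Each block haplotype carries
the score $\sum_{l \in b} \beta_l G_{l,m,i}$ and is inherited
atomically — within-block recombination is ignored after aggregation,
the standard optimal-haploid-value style approximation that the
aggregation exists to enable. GEBVs are preserved exactly. The
recombination frequency between adjacent blocks aggregates the
intervals between the two blocks' midpoint loci as
$1 - \prod_l (1-r_l)$, capped at 0.5; this reduces to $r_l$ at the
identity partition. The genetic potentials of a blocked population are
the blocked analogues (extremes over block scores); they nest inside
the SNP-level bounds and coincide at the identity partition.

## Program evaluation

Each generation records four criteria on the fresh progeny population:
mean GEBV; the lower and upper genetic potentials
$2\sum_l \min_{m,i} G_{l,m,i}\beta_l$ and
$2\sum_l \max_{m,i} G_{l,m,i}\beta_l$ (bounds on reachable GEBV given
the alleles still segregating — diversity proxies; the overall mean is
excluded, following the printed criterion definitions); and, at the end
of the program, the present value of gains
$\sum_{\tau=1}^{T} \max_i v_i^{(\tau)} / (1+\lambda_{\mathrm{eval}})^\tau$.
The evaluation discount rate defaults to the objective's $\lambda$ but
is exposed separately (`evalLambda`), so sensitivity arms with
different objective $\lambda$ can still be scored on a common scale.
Because meiosis never creates alleles, the upper potential is
non-increasing and the lower potential non-decreasing across
generations — asserted over every simulated program in the test suite.

## Synthetic data and what it does (not) show

The generator emulates an inbred founder panel: haplotype 1 is drawn
with locus-specific major-allele frequencies (default
$p_l \sim U(0.1, 0.9)$) and copied to haplotype 2, mirroring
fully homozygous inbred lines; a heterozygous mode exists for
generality. Effects are sparse mixed-sign draws (default: nonzero with
probability 0.1, standard normal scale), and maps place loci evenly on
chromosomes with i.i.d. within-chromosome recombination frequencies
uniform on $(0, 2\bar r]$. No linkage disequilibrium or coalescent
structure is simulated: passing tests demonstrate the selection
machinery's behavior under the assumed additive/Markov model, not
performance on real LD structure, and real panels will differ in the
distribution of favorable haplotypes available to stack.

The replicated comparison in the test suite and acceptance script runs
a deliberately scaled-down study: a pool of 100 inbred founders at
L = 1000 markers on 4 chromosomes (about 5 Morgans in total,
aggregated to 200 blocks), N = 50 individuals per generation, S = 5
crosses, T = 8 generations, W = 3, $\lambda = 0.1$, $\gamma = 0.8$,
K = 200 simulated progeny, and 50 replicates per method with common
founder seeds across methods. These sizes keep a full three-method
comparison under a minute while leaving the directional conclusions
(PV-LAS > LAS > CGS in present value; PV-LAS at least matches LAS in
early-generation mean gains) statistically resolvable by paired sign
tests.

One directional claim does not reproduce under these normalizations:
raising the objective discount rate from 0 to 0.5 does not detectably
raise generation-1 mean GEBV. With inbred founders the $\tau = 1$
progeny of each cross is deterministic, so the $\gamma$-quantile of the
random-progeny mixture sees S atoms and most paired replicates select
identical first plans in both arms; among the rest the direction is
absent. Mechanistically, weighting $\psi_1$ more heavily optimizes the
top quintile of the progeny mixture — which can be served by one elite
cross — rather than the population mean; the W = 1 versus W = 3
contrast shows this at full strength (W = 1 *lowers* generation-1 mean
gains by about 3.6 trait units here while jumping generation-2 gains,
then plateaus far below, the expected early-jump-then-stagnate
signature in amplified form). The long-term half of the discount-rate
claim — larger $\lambda$ weakens later generations — reproduces
robustly. Optimizing per-cross progeny allocation, which would couple
the quantile objective to the population mean, is deliberately out of
scope (every cross contributes N/S progeny).

## Numerical and degenerate-input choices

* Quantile = order statistic at rank $\lceil \gamma K \rceil$; ties and
  degenerate distributions need no special casing.
* Truncation ties in CGS and warm starts break by ascending index;
  exhaustive-search ties break lexicographically on the sorted pair
  list.
* All recombination inputs are validated into $[0, 0.5]$ with
  boundary intervals forced to 0.5; the cM-to-r conversion uses
  Haldane's function $r = \tfrac12(1 - e^{-2d/100})$, consistent with
  the no-interference meiosis model (Kosambi would presume
  interference the simulator does not model).
* A monomorphic population is a fixed point: every method returns
  feasible plans and all metrics are constant.
* Replicate seeds derive deterministically from one master seed;
  identical configuration and seed give byte-identical outputs.

## Limitations

Single additive trait; diploids; non-overlapping generations; equal
resource allocation across crosses; Monte-Carlo (not analytic)
quantiles; no mutation, interference, or LD-aware founder simulation.
The local search is a heuristic: no global-optimality guarantee is
claimed beyond the small-instance comparisons above.
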