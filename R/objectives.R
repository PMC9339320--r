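#' Empirical gamma-quantile of a Monte-Carlo sample
#'
#' The ascending order statistic at rank \eqn{\lceil \gamma K \rceil}: the
#' largest value phi such that a random draw is >= phi with empirical
#' probability at least 1 - gamma. No interpolation, so the result is
#' always one of the samples and exactly reproducible.
#'
#' @param samples numeric vector of K simulated values.
#' @param gamma quantile parameter in (0, 1).
#' @return A single number.
#' @examples
#' gammaQuantile(sample(1:10), 0.8)  # 8
#' @export
gammaQuantile <- function(samples, gamma) {
  K <- length(samples)
  if (K < 1L) argError("empty sample vector")
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1)
    argError("gamma must lie in (0, 1)")
  sort(samples, method = "quick")[ceiling(gamma * K)]
}

#' Conventional genomic-selection score
#'
#' Total GEBV of the selected breeding parents,
#' \eqn{f(x, G) = \sum_i x_i v_i}: the objective of truncation selection.
#'
#' @param v numeric GEBV vector of length N.
#' @param x binary selection indicator vector of length N; must select
#'   2S individuals unless `S = NULL`.
#' @param S number of crosses (used to validate `sum(x) == 2S`); NULL
#'   skips the count check.
#' @return A single number.
#' @export
cgsScore <- function(v, x, S = NULL) {
  if (length(x) != length(v)) argError("x and v lengths differ")
  if (!all(x %in% c(0, 1))) argError("x must be binary")
  if (!is.null(S) && sum(x) != 2 * S)
    argError("selection count %d differs from 2S = %d", sum(x), 2 * S)
  sum(x * v)
}

# shared core: psi_tau over a set of offsets, via the descendant simulator
psiQuantiles <- function(x, crosses, taus, trait, map, spec) {
  vapply(taus, function(tau) {
    s <- simulateDescendantProgeny(x, crosses, tau, trait = trait,
                                   map = map, K = spec@K)
    gammaQuantile(s, spec@gamma)
  }, numeric(1))
}

#' Look-ahead selection objective
#'
#' \eqn{\phi}: the gamma-quantile of a random progeny's GEBV simulated at
#' the remaining horizon T - t (the deadline generation), the quantity LAS
#' maximizes over mating plans.
#'
#' @param x a [PhasedGenotypes-class] or [BlockedPopulation-class].
#' @param crosses a [MatingPlan-class].
#' @param trait,map required for phased genotypes.
#' @param horizon remaining generations to the deadline, >= 1.
#' @param spec a [LookAheadSpec-class]; `gamma` and `K` are used.
#' @return An [ObjectiveValue-class] with `phi` set (and `psi` holding the
#'   single horizon quantile).
#' @export
lasObjective <- function(x, crosses, trait = NULL, map = NULL, horizon,
                         spec = LookAheadSpec()) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) argError("horizon must be >= 1")
  phi <- psiQuantiles(x, crosses, horizon, trait, map, spec)
  new("ObjectiveValue", zeta = NA_real_, phi = phi, psi = phi,
      lambda = spec@lambda)
}

#' Present-value look-ahead selection objective
#'
#' \eqn{\zeta(x, Y) = \sum_{\tau=1}^{W} \psi_\tau / (1+\lambda)^\tau},
#' where \eqn{\psi_\tau} is the gamma-quantile of a random progeny's GEBV
#' simulated tau generations ahead: the discounted present value of the
#' quantile gains over the sliding window that PV-LAS maximizes.
#'
#' @inheritParams lasObjective
#' @param spec a [LookAheadSpec-class]; all four fields are used.
#' @return An [ObjectiveValue-class] with `zeta` and the full `psi`
#'   vector.
#' @export
pvlasObjective <- function(x, crosses, trait = NULL, map = NULL,
                           spec = LookAheadSpec()) {
  psi <- psiQuantiles(x, crosses, seq_len(spec@W), trait, map, spec)
  zeta <- sum(psi / (1 + spec@lambda)^seq_len(spec@W))
  new("ObjectiveValue", zeta = zeta, phi = NA_real_, psi = psi,
      lambda = spec@lambda)
}
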