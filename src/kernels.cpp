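#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// uniform integer in 0..n-1 drawn from R's RNG
static inline int unif_int(int n) {
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// Sample n gametes from one diploid parent. First-order Markov walk along
// the chromosome: the source haplotype at the first locus is uniform over
// the two parental haplotypes and switches with probability r[l] at
// interval l (r <= 0.5 by the map invariant). Works on arbitrary numeric
// per-locus values, so the same kernel serves 0/1 allele vectors and
// block score vectors.
// [[Rcpp::export(name = ".cppMeiosisGametes")]]
NumericMatrix cppMeiosisGametes(NumericVector h1, NumericVector h2,
                                NumericVector r, int n) {
  int L = h1.size();
  NumericMatrix out(L, n);
  for (int s = 0; s < n; ++s) {
    int src = (unif_rand() < 0.5) ? 1 : 0;
    out(0, s) = src ? h2[0] : h1[0];
    for (int l = 1; l < L; ++l) {
      if (unif_rand() < r[l - 1]) src = 1 - src;
      out(l, s) = src ? h2[l] : h1[l];
    }
  }
  return out;
}

// Recombination trajectories of 2K descendant gametes (two per progeny),
// tau generations ahead of a plan of S crosses, encoded as runs of
// constant source haplotype: segment arrays segEnd / segCol plus per-
// gamete offsets gamStart (0-based, length 2K + 1). Column indices refer
// to the loci x 4S pool matrix whose columns 4c..4c+3 are the four
// haplotypes of cross c. The trajectory depends only on (r, S, tau), not
// on the haplotype values, which is what makes frozen common-random-
// number evaluation of candidate plans possible.
//
// tau == 1: both gametes of a progeny come from one uniformly chosen
// cross, one single-meiosis gamete per parent. tau >= 2: each gamete is
// an independent Markov mosaic over the pool; at interval l it migrates
// to a uniformly chosen haplotype of a different cross with probability
// Rtilde_l(tau) = (S-1)[1-(1-r_l)^tau]/S for tau >= 3 (zero below),
// otherwise switches to one of the other three haplotypes of its cross
// with probability 1-(1-r_l)^tau. Effective probabilities are capped at
// 0.5.
// [[Rcpp::export(name = ".cppSampleSegments")]]
List cppSampleSegments(NumericVector r, int S, int tau, int K) {
  int nInt = r.size();
  int B = nInt + 1;
  int nGam = 2 * K;
  std::vector<int> gamStart(nGam + 1);
  std::vector<int> segEnd, segCol;
  segEnd.reserve(4 * nGam);
  segCol.reserve(4 * nGam);

  if (tau == 1) {
    int cross = 0;
    for (int g = 0; g < nGam; ++g) {
      gamStart[g] = (int)segEnd.size();
      if (g % 2 == 0) cross = unif_int(S);
      int base = 4 * cross + 2 * (g % 2);
      int src = unif_int(2);
      int runStart = 1;
      for (int l = 0; l < nInt; ++l) {
        if (unif_rand() < r[l]) {
          segEnd.push_back(l + 1);   // run covered blocks runStart..l+1
          segCol.push_back(base + src);
          src = 1 - src;
          runStart = l + 2;
        }
      }
      segEnd.push_back(B);
      segCol.push_back(base + src);
      (void)runStart;
    }
  } else {
    std::vector<double> q(nInt > 0 ? nInt : 1), Rl(nInt > 0 ? nInt : 1);
    for (int l = 0; l < nInt; ++l) {
      double w = 1.0 - std::pow(1.0 - r[l], (double)tau);
      q[l] = (w < 0.5) ? w : 0.5;
      double rr = (S > 1 && tau >= 3) ? (S - 1) * w / (double)S : 0.0;
      Rl[l] = (rr < 0.5) ? rr : 0.5;
    }
    for (int g = 0; g < nGam; ++g) {
      gamStart[g] = (int)segEnd.size();
      int cross = unif_int(S);
      int slot = unif_int(4);
      for (int l = 0; l < nInt; ++l) {
        double u = unif_rand();
        bool moved = false;
        if (u < Rl[l]) {
          int oth = unif_int(S - 1);
          if (oth >= cross) ++oth;
          segEnd.push_back(l + 1);
          segCol.push_back(4 * cross + slot);
          cross = oth;
          slot = unif_int(4);
          moved = true;
        } else if (u < Rl[l] + (1.0 - Rl[l]) * q[l]) {
          segEnd.push_back(l + 1);
          segCol.push_back(4 * cross + slot);
          slot = (slot + 1 + unif_int(3)) % 4;
          moved = true;
        }
        (void)moved;
      }
      segEnd.push_back(B);
      segCol.push_back(4 * cross + slot);
    }
  }
  gamStart[nGam] = (int)segEnd.size();
  return List::create(_["gamStart"] = wrap(gamStart),
                      _["segEnd"] = wrap(segEnd),
                      _["segCol"] = wrap(segCol));
}

// Progeny scores from sampled trajectories: per-column cumulative sums of
// the pool matrix turn each constant-source run into one subtraction;
// progeny k sums gametes 2k and 2k+1. Returns K values (no intercept).
// [[Rcpp::export(name = ".cppSegmentScores")]]
NumericVector cppSegmentScores(NumericMatrix pool, IntegerVector gamStart,
                               IntegerVector segEnd, IntegerVector segCol) {
  int B = pool.nrow();
  int nCol = pool.ncol();
  std::vector<double> csum((size_t)B * nCol);
  for (int c = 0; c < nCol; ++c) {
    double acc = 0.0;
    const double *src = &pool(0, c);
    double *dst = &csum[(size_t)c * B];
    for (int b = 0; b < B; ++b) {
      acc += src[b];
      dst[b] = acc;
    }
  }
  int nGam = gamStart.size() - 1;
  int K = nGam / 2;
  NumericVector out(K);
  for (int g = 0; g < nGam; ++g) {
    double tot = 0.0;
    int prevEnd = 0;
    for (int s = gamStart[g]; s < gamStart[g + 1]; ++s) {
      const double *col = &csum[(size_t)segCol[s] * B];
      int e = segEnd[s];
      tot += col[e - 1] - (prevEnd > 0 ? col[prevEnd - 1] : 0.0);
      prevEnd = e;
    }
    out[g / 2] += tot;
  }
  return out;
}

// Incremental candidate evaluation for one local-search slot. For the
// slot (cross slotIdx, parent position side) of the incumbent plan, all
// candidate replacement parents are scored against the SAME frozen
// trajectories: gamete scores over segments not touching slotIdx are
// accumulated once, and each candidate only re-scores the segments that
// copy from the modified cross. Returns the objective
// sum_t weights[t] * psi_t(candidate), with psi_t the gamma-quantile of
// the K progeny scores (mu added) at offset t.
//
// s1, s2: B x N per-haplotype value matrices; pairs: S x 2 (1-based);
// segsList: per-offset trajectory lists from .cppSampleSegments;
// candidates: 1-based candidate parent indices.
// [[Rcpp::export(name = ".cppEvalReplacements")]]
NumericVector cppEvalReplacements(NumericMatrix s1, NumericMatrix s2,
                                  IntegerMatrix pairs, int slotIdx,
                                  int side, IntegerVector candidates,
                                  List segsList, NumericVector weights,
                                  double gammaq, double mu) {
  int B = s1.nrow(), N = s1.ncol(), S = pairs.nrow();
  int nT = segsList.size();
  // column cumsums of all 2N haplotype value vectors
  std::vector<double> HC((size_t)B * 2 * N);
  for (int i = 0; i < N; ++i) {
    double a = 0.0, b = 0.0;
    const double *c1 = &s1(0, i), *c2 = &s2(0, i);
    double *d1 = &HC[(size_t)i * B], *d2 = &HC[(size_t)(N + i) * B];
    for (int bb = 0; bb < B; ++bb) {
      a += c1[bb]; d1[bb] = a;
      b += c2[bb]; d2[bb] = b;
    }
  }
  // Candidate pairs are stored sorted (parent1 <= parent2), exactly as a
  // MatingPlan normalizes them, so the evaluation here matches a fresh
  // evaluation of the stored neighbor plan bit for bit.
  int keep = pairs(slotIdx, side == 0 ? 1 : 0) - 1;
  auto hapCol = [&](int c, int m, int repl) -> int {
    int pos = m / 2, hap = m % 2;
    int ind;
    if (c == slotIdx) {
      int p1 = keep < repl ? keep : repl;
      int p2 = keep < repl ? repl : keep;
      ind = pos == 0 ? p1 : p2;
    } else ind = pairs(c, pos) - 1;
    return hap == 0 ? ind : N + ind;
  };
  int nCand = candidates.size();
  // per offset: base score per gamete + segments touching the slot
  std::vector<std::vector<double>> base(nT);
  std::vector<std::vector<int>> mg(nT), mstart(nT), mend(nT), mslot(nT);
  int K = 0;
  for (int t = 0; t < nT; ++t) {
    List sg = segsList[t];
    IntegerVector gamStart = sg["gamStart"];
    IntegerVector segEnd = sg["segEnd"];
    IntegerVector segCol = sg["segCol"];
    int nGam = gamStart.size() - 1;
    K = nGam / 2;
    base[t].assign(nGam, 0.0);
    for (int g = 0; g < nGam; ++g) {
      int prevEnd = 0;
      for (int s = gamStart[g]; s < gamStart[g + 1]; ++s) {
        int col = segCol[s], e = segEnd[s];
        int c = col / 4, m = col % 4;
        if (c == slotIdx) {
          mg[t].push_back(g);
          mstart[t].push_back(prevEnd);
          mend[t].push_back(e);
          mslot[t].push_back(m);
        } else {
          const double *cs = &HC[(size_t)hapCol(c, m, -1) * B];
          base[t][g] += cs[e - 1] - (prevEnd > 0 ? cs[prevEnd - 1] : 0.0);
        }
        prevEnd = e;
      }
    }
  }
  NumericVector out(nCand);
  std::vector<double> sc, prog(K);
  int rank = (int)std::ceil(gammaq * K) - 1;
  if (rank < 0) rank = 0;
  if (rank >= K) rank = K - 1;
  for (int ci = 0; ci < nCand; ++ci) {
    int repl = candidates[ci] - 1;
    double obj = 0.0;
    for (int t = 0; t < nT; ++t) {
      sc = base[t];
      const size_t nm = mg[t].size();
      for (size_t s = 0; s < nm; ++s) {
        const double *cs =
          &HC[(size_t)hapCol(slotIdx, mslot[t][s], repl) * B];
        int e = mend[t][s], st = mstart[t][s];
        sc[mg[t][s]] += cs[e - 1] - (st > 0 ? cs[st - 1] : 0.0);
      }
      for (int p = 0; p < K; ++p)
        prog[p] = sc[2 * p] + sc[2 * p + 1] + mu;
      std::nth_element(prog.begin(), prog.begin() + rank, prog.end());
      obj += weights[t] * prog[rank];
    }
    out[ci] = obj;
  }
  return out;
}
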