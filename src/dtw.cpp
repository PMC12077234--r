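#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping between two univariate sequences.
// Local cost |a_i - b_j|, symmetric steps {(1,0),(0,1),(1,1)}.
// Among all minimum-total-cost warping paths the shortest one is selected
// (lexicographic minimisation of (total cost, path length)), and the
// returned distance is total cost divided by that path length when
// normalize is true. Lexicographic additive objectives preserve optimal
// substructure, so a plain DP is exact.
// [[Rcpp::export]]
double dtw_core(NumericVector a, NumericVector b, bool normalize) {
  int n = a.size(), m = b.size();
  if (n < 2 || m < 2) stop("traces must have length >= 2");
  NumericMatrix cost(n, m);
  IntegerMatrix len(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(a[i] - b[j]);
      if (i == 0 && j == 0) {
        cost(i, j) = c;
        len(i, j) = 1;
        continue;
      }
      double best = R_PosInf;
      int bestLen = INT_MAX;
      // predecessors: diagonal, up, left
      int pi[3] = {i - 1, i - 1, i};
      int pj[3] = {j - 1, j, j - 1};
      for (int k = 0; k < 3; ++k) {
        if (pi[k] < 0 || pj[k] < 0) continue;
        double pc = cost(pi[k], pj[k]);
        int pl = len(pi[k], pj[k]);
        if (pc < best - 1e-12 || (std::abs(pc - best) <= 1e-12 && pl < bestLen)) {
          best = pc;
          bestLen = pl;
        }
      }
      cost(i, j) = best + c;
      len(i, j) = bestLen + 1;
    }
  }
  double total = cost(n - 1, m - 1);
  if (normalize) return total / len(n - 1, m - 1);
  return total;
}
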