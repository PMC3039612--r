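#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap pairwise alignment over a precomputed position score matrix C
// (C[i,j] = substitution score of residue i of `a` against residue j of `b`).
// A gap of length L costs open + (L-1) * extend.
//
// Traceback tie order: diagonal (match/mismatch) first, then gap in `a`
// (consume b), then gap in `b` (consume a), so results are deterministic.
//
// local = false: Needleman-Wunsch, end-to-end.
// local = true:  Smith-Waterman, best-scoring local path.
//
// Returns score and the aligned index vectors ai, bi (0 = gap).
// [[Rcpp::export]]
List pairdp_cpp(NumericMatrix C, double gap_open, double gap_extend, bool local) {
  const int n = C.nrow(), m = C.ncol();
  const double NEG = -1e30;
  // Layered DP: M ends in diagonal, X ends in gap-in-a (consumes b[j]),
  // Y ends in gap-in-b (consumes a[i]).
  std::vector<double> M((n + 1) * (m + 1), NEG), X(M), Y(M);
  std::vector<uint8_t> tbM(M.size(), 0), tbX(M.size(), 0), tbY(M.size(), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    X[at(0, j)] = -(gap_open + (j - 1) * gap_extend);
    tbX[at(0, j)] = 1; // came from X (or M at j==1)
    if (local) X[at(0, j)] = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    Y[at(i, 0)] = -(gap_open + (i - 1) * gap_extend);
    tbY[at(i, 0)] = 2;
    if (local) Y[at(i, 0)] = NEG;
  }
  if (local)
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= m; ++j)
        if (i == 0 || j == 0) M[at(i, j)] = 0.0;

  double best = 0.0; int bi_ = 0, bj_ = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j);
      // M: from any layer at (i-1, j-1)
      const int d = at(i - 1, j - 1);
      double s = M[d]; uint8_t t = 0;
      if (X[d] > s) { s = X[d]; t = 1; }
      if (Y[d] > s) { s = Y[d]; t = 2; }
      double mv = s + C(i - 1, j - 1);
      if (local && mv < 0.0) { mv = 0.0; t = 3; } // 3 = local start
      M[ij] = mv; tbM[ij] = t;
      // X: gap in a, consume b[j]; open from M/Y, extend from X
      const int l = at(i, j - 1);
      double xo = std::max(M[l], Y[l]) - gap_open;
      double xe = X[l] - gap_extend;
      if (xo >= xe) { X[ij] = xo; tbX[ij] = (M[l] >= Y[l]) ? 0 : 2; }
      else          { X[ij] = xe; tbX[ij] = 1; }
      // Y: gap in b, consume a[i]
      const int u = at(i - 1, j);
      double yo = std::max(M[u], X[u]) - gap_open;
      double ye = Y[u] - gap_extend;
      if (yo >= ye) { Y[ij] = yo; tbY[ij] = (M[u] >= X[u]) ? 0 : 1; }
      else          { Y[ij] = ye; tbY[ij] = 2; }
      if (local && M[ij] > best) { best = M[ij]; bi_ = i; bj_ = j; }
    }
  }

  int i, j, layer; double score;
  if (local) {
    score = best; i = bi_; j = bj_; layer = 0;
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0,
                          _["ai"] = IntegerVector(0), _["bi"] = IntegerVector(0));
    }
  } else {
    const int e = at(n, m);
    score = M[e]; layer = 0;
    if (X[e] > score) { score = X[e]; layer = 1; }
    if (Y[e] > score) { score = Y[e]; layer = 2; }
    i = n; j = m;
  }

  std::vector<int> ra, rb;
  while (i > 0 || j > 0) {
    if (local && layer == 0 && M[at(i, j)] == 0.0 && tbM[at(i, j)] == 3) break;
    if (layer == 0) {
      if (i == 0 || j == 0) break; // global edge handled by X/Y layers only
      uint8_t t = tbM[at(i, j)];
      ra.push_back(i); rb.push_back(j);
      --i; --j;
      if (local && t == 3) break;
      layer = (t == 3) ? 0 : t;
      if (local && i == 0 && j == 0) break;
    } else if (layer == 1) {
      ra.push_back(0); rb.push_back(j);
      layer = tbX[at(i, j)];
      --j;
    } else {
      ra.push_back(i); rb.push_back(0);
      layer = tbY[at(i, j)];
      --i;
    }
    if (local && i == 0 && j == 0) break;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score,
                      _["ai"] = IntegerVector(ra.begin(), ra.end()),
                      _["bi"] = IntegerVector(rb.begin(), rb.end()));
}

// Sum of position-specific log-odds over every window of the encoded sequence.
// enc: 1-based residue codes (columns of lo); lo: profile_length x n_codes.
// [[Rcpp::export]]
NumericVector profile_scan_cpp(IntegerVector enc, NumericMatrix lo) {
  const int n = enc.size(), L = lo.nrow();
  if (n < L) return NumericVector(0);
  NumericVector out(n - L + 1);
  for (int s = 0; s + L <= n; ++s) {
    double acc = 0.0;
    for (int k = 0; k < L; ++k) acc += lo(k, enc[s + k] - 1);
    out[s] = acc;
  }
  return out;
}

// Pairwise-deletion mismatch proportions over selected alignment columns.
// M: n x L integer codes, 0 = gap; cols: 1-based column indices (resampled
// or identity). Returns p-distance matrix; shared-site counts as attribute.
// [[Rcpp::export]]
List pdist_cpp(IntegerMatrix M, IntegerVector cols) {
  const int n = M.nrow(), L = cols.size();
  NumericMatrix P(n, n);
  IntegerMatrix SH(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int shared = 0, mism = 0;
      for (int c = 0; c < L; ++c) {
        const int cc = cols[c] - 1;
        const int a = M(i, cc), b = M(j, cc);
        if (a > 0 && b > 0) { ++shared; if (a != b) ++mism; }
      }
      SH(i, j) = SH(j, i) = shared;
      P(i, j) = P(j, i) = shared > 0 ? (double)mism / shared : NA_REAL;
    }
  }
  return List::create(_["p"] = P, _["shared"] = SH);
}
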