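#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with affine gaps (Gotoh) over a precomputed column-score
// matrix S (n x m): S(i,j) is the score of pairing column i of the first
// profile with column j of the second. A gap of length L costs
// open + (L-1) * extend. Works both for plain sequence pairs (S from the
// substitution matrix) and for profile-profile merges (S from sum-of-pairs
// column scores).
//
// Returns the optimal score and a move vector over the optimal path:
// 1 = pair columns, 2 = column of A against gap, 3 = column of B against gap.
// Tie-break, applied consistently in the DP and the traceback: pairing beats
// a gap in the second profile, which beats a gap in the first.

static const double NEG_INF = -1e300;

// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double open, double extend) {
  const int n = S.nrow(), m = S.ncol();
  // state matrices: M (pair), X (gap in B, consumes A), Y (gap in A, consumes B)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = open + (i - 1) * extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = open + (j - 1) * extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      M(i, j) = best + S(i - 1, j - 1);

      double xo = std::max(M(i - 1, j), Y(i - 1, j)) + open;
      double xe = X(i - 1, j) + extend;
      X(i, j) = std::max(xo, xe);

      double yo = std::max(M(i, j - 1), X(i, j - 1)) + open;
      double ye = Y(i, j - 1) + extend;
      Y(i, j) = std::max(yo, ye);
    }
  }

  double score = M(n, m);
  int state = 1;                      // 1 = M, 2 = X, 3 = Y (preference order)
  if (X(n, m) > score) { score = X(n, m); state = 2; }
  if (Y(n, m) > score) { score = Y(n, m); state = 3; }

  std::vector<int> rev;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { rev.push_back(3); --j; continue; }
    if (j == 0) { rev.push_back(2); --i; continue; }
    if (state == 1) {
      rev.push_back(1);
      double t = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M(i, j) - t) < 1e-9) state = 1;
      else if (std::abs(X(i, j) - t) < 1e-9) state = 2;
      else state = 3;
    } else if (state == 2) {
      rev.push_back(2);
      double t = X(i, j);
      --i;
      if (std::abs(M(i, j) + open - t) < 1e-9) state = 1;
      else if (std::abs(X(i, j) + extend - t) < 1e-9) state = 2;
      else state = 3;
    } else {
      rev.push_back(3);
      double t = Y(i, j);
      --j;
      if (std::abs(M(i, j) + open - t) < 1e-9) state = 1;
      else if (std::abs(X(i, j) + open - t) < 1e-9) state = 2;
      else state = 3;
    }
  }
  IntegerVector moves(rev.size());
  for (size_t k = 0; k < rev.size(); ++k) moves[k] = rev[rev.size() - 1 - k];
  return List::create(_["score"] = score, _["moves"] = moves);
}
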