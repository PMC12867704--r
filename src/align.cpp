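#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Needleman-Wunsch-Gotoh).
// Gap run of length L scores open + (L-1)*extend; end gaps are penalized.
// Tie-break in traceback: M (diagonal) preferred, then gap in query b
// (consume a only), then gap in a. This makes the traceback deterministic
// and pushes gaps in the query toward the end of the path.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix score,
                 double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // M: a[i] aligned to b[j]; X: gap in b (consume a); Y: gap in a (consume b)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF;
    X(i, 0) = gap_open + (i - 1) * gap_extend;
    Y(i, 0) = NEG_INF;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF;
    X(0, j) = NEG_INF;
    Y(0, j) = gap_open + (j - 1) * gap_extend;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = score(a[i - 1] - 1, b[j - 1] - 1);
      double prev = std::max(M(i - 1, j - 1),
                             std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = prev + s;
      X(i, j) = std::max(M(i - 1, j) + gap_open,
                         std::max(X(i - 1, j) + gap_extend,
                                  Y(i - 1, j) + gap_open));
      Y(i, j) = std::max(M(i, j - 1) + gap_open,
                         std::max(Y(i, j - 1) + gap_extend,
                                  X(i, j - 1) + gap_open));
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));

  // traceback; state 0 = M, 1 = X (gap in b), 2 = Y (gap in a)
  std::vector<int> ops; // 0 diag, 1 consume a, 2 consume b
  int i = n, j = m;
  int state;
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 0;
  else if (X(n, m) >= Y(n, m)) state = 1;
  else state = 2;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ops.push_back(0);
      double s = score(a[i - 1] - 1, b[j - 1] - 1);
      double target = M(i, j) - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M(i, j) - target) < eps) state = 0;
      else if (std::abs(X(i, j) - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back(1);
      double target = X(i, j);
      --i;
      if (std::abs(M(i, j) + gap_open - target) < eps) state = 0;
      else if (std::abs(X(i, j) + gap_extend - target) < eps) state = 1;
      else state = 2;
      if (i == 0 && j == 0) break;
    } else {
      ops.push_back(2);
      double target = Y(i, j);
      --j;
      if (std::abs(M(i, j) + gap_open - target) < eps) state = 0;
      else if (std::abs(Y(i, j) + gap_extend - target) < eps) state = 2;
      else state = 1;
      if (i == 0 && j == 0) break;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
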