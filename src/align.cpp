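#include <Rcpp.h>
using namespace Rcpp;

// Three-state (Gotoh) global alignment with affine gaps.
// States: 0 = M (substitution), 1 = X (gap in query, ref residue consumed),
//         2 = Y (gap in ref, query residue consumed).
// A gap run of length L costs open + (L - 1) * ext.
// Ties are broken by state preference M > X > Y, applied both to the final
// cell and to every predecessor choice, which fixes a unique traceback.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List align_affine_cpp(IntegerVector ref, IntegerVector query,
                      NumericMatrix sub, double open, double ext) {
  const int m = ref.size(), n = query.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");

  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  // predecessor state per cell/state, -1 = none
  IntegerMatrix pm(m + 1, n + 1), px(m + 1, n + 1), py(m + 1, n + 1);

  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) {
      M(i, j) = X(i, j) = Y(i, j) = NEG_INF;
      pm(i, j) = px(i, j) = py(i, j) = -1;
    }
  M(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) {
    X(i, 0) = open + (i - 1) * ext;
    px(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    Y(0, j) = open + (j - 1) * ext;
    py(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M: consume ref[i-1] with query[j-1]
      double s = sub(ref[i - 1], query[j - 1]);
      double cand[3] = { M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1) };
      int best = 0;
      for (int k = 1; k < 3; ++k) if (cand[k] > cand[best]) best = k;
      if (cand[best] > NEG_INF / 2) {
        M(i, j) = cand[best] + s;
        pm(i, j) = best;
      }
      // X: gap in query (ref residue vs '-')
      double cx[3] = { M(i - 1, j) + open, X(i - 1, j) + ext, Y(i - 1, j) + open };
      best = 0;
      for (int k = 1; k < 3; ++k) if (cx[k] > cx[best]) best = k;
      if (cx[best] > NEG_INF / 2) {
        X(i, j) = cx[best];
        px(i, j) = best;
      }
      // Y: gap in ref ('-' vs query residue)
      double cy[3] = { M(i, j - 1) + open, X(i, j - 1) + open, Y(i, j - 1) + ext };
      best = 0;
      for (int k = 1; k < 3; ++k) if (cy[k] > cy[best]) best = k;
      if (cy[best] > NEG_INF / 2) {
        Y(i, j) = cy[best];
        py(i, j) = best;
      }
    }
  }

  double fin[3] = { M(m, n), X(m, n), Y(m, n) };
  int st = 0;
  for (int k = 1; k < 3; ++k) if (fin[k] > fin[st]) st = k;
  double score = fin[st];

  // traceback: collect moves (state at each consumed column), reversed
  std::vector<int> path;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    path.push_back(st);
    int prev;
    if (st == 0)      { prev = pm(i, j); --i; --j; }
    else if (st == 1) { prev = px(i, j); --i; }
    else              { prev = py(i, j); --j; }
    st = prev;
  }
  std::reverse(path.begin(), path.end());

  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
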