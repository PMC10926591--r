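#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh, three-state DP with full traceback).
// a, b: 1-based indices into the substitution matrix.
// A gap of length L costs gap_open + (L-1) * gap_extend.
// Tie-breaking is deterministic: diagonal (match state) is preferred, then
// up (gap in b), then left (gap in a), both when choosing the predecessor
// state inside each recurrence and when choosing the final state.

static const double NINF = -1e18;

// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  // state matrices: 0 = M (a_i ~ b_j), 1 = X (a_i ~ gap), 2 = Y (gap ~ b_j)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix bM(n + 1, m + 1), bX(n + 1, m + 1), bY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NINF; Y(0, 0) = NINF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NINF; Y(i, 0) = NINF;
    X(i, 0) = -gap_open - (i - 1) * gap_extend;
    bX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NINF; X(0, j) = NINF;
    Y(0, j) = -gap_open - (j - 1) * gap_extend;
    bY(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      // M: prefer M, then X, then Y
      double vm = M(i - 1, j - 1), vx = X(i - 1, j - 1), vy = Y(i - 1, j - 1);
      int arg = 0; double best = vm;
      if (vx > best) { best = vx; arg = 1; }
      if (vy > best) { best = vy; arg = 2; }
      M(i, j) = best + s; bM(i, j) = arg;
      // X: gap in b, consuming a_i (move up)
      vm = M(i - 1, j) - gap_open;
      vx = X(i - 1, j) - gap_extend;
      vy = Y(i - 1, j) - gap_open;
      arg = 0; best = vm;
      if (vx > best) { best = vx; arg = 1; }
      if (vy > best) { best = vy; arg = 2; }
      X(i, j) = best; bX(i, j) = arg;
      // Y: gap in a, consuming b_j (move left)
      vm = M(i, j - 1) - gap_open;
      vx = X(i, j - 1) - gap_open;
      vy = Y(i, j - 1) - gap_extend;
      arg = 0; best = vm;
      if (vx > best) { best = vx; arg = 1; }
      if (vy > best) { best = vy; arg = 2; }
      Y(i, j) = best; bY(i, j) = arg;
    }
  }

  int state = 0;
  double score = M(n, m);
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> pa, pb;  // 0 = gap, else 1-based position
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = bM(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = bX(i, j);
      pa.push_back(i); pb.push_back(0);
      --i; state = prev;
    } else {
      int prev = bY(i, j);
      pa.push_back(0); pb.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score,
                      _["pos_a"] = wrap(pa), _["pos_b"] = wrap(pb));
}
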