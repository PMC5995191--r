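#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global (Needleman-Wunsch/Gotoh) alignment over a precomputed
// column-score matrix S (rows = positions of the first profile, cols =
// positions of the second). A gap run of length g costs gapOpen + g*gapExt.
// Traceback is deterministic "high road": on ties prefer a match, then
// consuming the first profile (gap in the second), then the reverse.
// Returns the optimal score and the move sequence (1 = match, 2 = gap in
// second profile, 3 = gap in first profile).

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".affine_dp")]]
List affine_dp(NumericMatrix S, double gapOpen, double gapExt) {
  const int n = S.nrow(), m = S.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) {
      M(i, j) = NEG_INF; X(i, j) = NEG_INF; Y(i, j) = NEG_INF;
    }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = -gapOpen - gapExt * i;
  for (int j = 1; j <= m; ++j) Y(0, j) = -gapOpen - gapExt * j;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double best = M(i - 1, j - 1);
      if (X(i - 1, j - 1) > best) best = X(i - 1, j - 1);
      if (Y(i - 1, j - 1) > best) best = Y(i - 1, j - 1);
      if (best > NEG_INF / 2) M(i, j) = best + S(i - 1, j - 1);

      double xo = M(i - 1, j) - gapOpen - gapExt;
      double xe = X(i - 1, j) - gapExt;
      double xy = Y(i - 1, j) - gapOpen - gapExt;
      double bx = xo >= xe ? xo : xe;
      if (xy > bx) bx = xy;
      X(i, j) = bx;

      double yo = M(i, j - 1) - gapOpen - gapExt;
      double yx = X(i, j - 1) - gapOpen - gapExt;
      double ye = Y(i, j - 1) - gapExt;
      double by = yo >= ye ? yo : ye;
      if (yx > by) by = yx;
      Y(i, j) = by;
    }
  }
  // also fill column/row zero X/Y transitions done in init

  int i = n, j = m;
  int state;  // 0 = M, 1 = X, 2 = Y, preference in that order
  double score = M(n, m); state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> moves;
  moves.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      moves.push_back(1);
      double prev = M(i, j) - S(i - 1, j - 1);
      --i; --j;
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      moves.push_back(2);
      double cur = X(i, j);
      --i;
      if (std::abs(M(i, j) - gapOpen - gapExt - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - gapExt - cur) < 1e-9) state = 1;
      else state = 2;
    } else {
      moves.push_back(3);
      double cur = Y(i, j);
      --j;
      if (std::abs(M(i, j) - gapOpen - gapExt - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - gapOpen - gapExt - cur) < 1e-9) state = 1;
      else state = 2;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = score,
                      _["moves"] = IntegerVector(moves.begin(), moves.end()));
}
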