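#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment DP over a precomputed column-score matrix.
// S[i, j] is the score for aligning unit i of sequence/profile A against
// unit j of B.  A gap of length L costs gap_open + L * gap_ext (the first
// gapped position pays open + ext).  local = Smith-Waterman semantics
// (score floored at 0, traceback from the best cell); otherwise global
// Needleman-Wunsch with end gaps penalized.
//
// Returns list(score, a_idx, b_idx): 1-based indices per alignment column,
// 0 marking a gap.  Traceback ties prefer diagonal > up (gap in B) > left.
// [[Rcpp::export(name = ".affine_align_cpp")]]
List affine_align_cpp(NumericMatrix S, double gap_open, double gap_ext,
                      bool local) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  const double go = gap_open + gap_ext;  // cost of first gapped position

  // M: column ends in a match; X: gap in B (consumes A); Y: gap in A.
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);
  // traceback codes: 1 = came from M, 2 = from X, 3 = from Y, 0 = fresh start

  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG; }
  M(0, 0) = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X(i, 0) = -(gap_open + i * gap_ext);
      tbX(i, 0) = (i == 1) ? 1 : 2;
    }
    for (int j = 1; j <= m; ++j) {
      Y(0, j) = -(gap_open + j * gap_ext);
      tbY(0, j) = (j == 1) ? 1 : 3;
    }
  }

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double d = dM; int td = 1;
      if (dX > d) { d = dX; td = 2; }
      if (dY > d) { d = dY; td = 3; }

      double mval; int tm;
      if (local && d <= 0.0) {        // never extend a non-positive prefix
        mval = S(i - 1, j - 1); tm = 0;
      } else {
        mval = d + S(i - 1, j - 1); tm = td;
      }
      M(i, j) = mval; tbM(i, j) = tm;

      double xo = M(i - 1, j) - go, xe = X(i - 1, j) - gap_ext;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 1; }
      else          { X(i, j) = xe; tbX(i, j) = 2; }

      double yo = M(i, j - 1) - go, ye = Y(i, j - 1) - gap_ext;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 1; }
      else          { Y(i, j) = ye; tbY(i, j) = 3; }

      if (local && mval > best) { best = mval; bi = i; bj = j; }
    }
  }

  int state = 1, i, j;
  double score;
  if (local) {
    if (best <= 0.0)
      return List::create(_["score"] = 0.0,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0));
    score = best; i = bi; j = bj;
  } else {
    double sM = M(n, m), sX = X(n, m), sY = Y(n, m);
    score = sM;
    if (sX > score) { score = sX; state = 2; }
    if (sY > score) { score = sY; state = 3; }
    i = n; j = m;
  }

  std::vector<int> ai, bi_;
  while (i > 0 || j > 0) {
    if (state == 1) {
      int prev = tbM(i, j);
      ai.push_back(i); bi_.push_back(j);
      --i; --j;
      if (local && prev == 0) break;  // this column started the alignment
      state = prev;
      if (prev == 0) break;           // global: reached (0,0)
    } else if (state == 2) {
      int prev = tbX(i, j);
      ai.push_back(i); bi_.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tbY(i, j);
      ai.push_back(0); bi_.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi_.begin(), bi_.end());

  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi_));
}
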